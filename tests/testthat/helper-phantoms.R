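# Small phantom configurations used throughout the unit tests; full-size
# (128 x 128 x 7) phantoms are reserved for the acceptance suite.

small_config <- function(aar_fraction = 0.5, is_fraction_of_aar = 0.5,
                         edema_extent_multiplier = 1, seed = 1L,
                         n_slices = 5L, matrix_size = 48L) {
  phantom_config(matrix_size = matrix_size, n_slices = n_slices,
                 r_outer = 9, r_inner = 5,
                 aar_fraction = aar_fraction,
                 is_fraction_of_aar = is_fraction_of_aar,
                 edema_extent_multiplier = edema_extent_multiplier,
                 seed = seed)
}

# a hand-buildable parameter map for threshold tests
manual_map <- function(values, valid = NULL, units = "a.u.") {
  if (is.null(valid)) valid <- array(TRUE, dim(values))
  aarcmr:::new_parameter_map(values, valid, quantity = "test", units = units)
}
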