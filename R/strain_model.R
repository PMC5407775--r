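#' Synthetic strain model
#'
#' Parameters of one simulated strain. `primary_efficiency` is the relative
#' rate at which primary piRNAs are sampled from the ancestral-TE fragments
#' carried by germline piRNA clusters -- the heritable determinant of
#' strain-to-strain variation in immunity emulated here. `pingpong_gain` is
#' the expected number of secondary (ping-pong) reads produced per primary
#' read for TEs flagged active. `maternal_transmission` is the fraction of
#' the ovarian piRNA rate carried into a 0--2 h embryo library.
#'
#' @param name strain name
#' @param primary_efficiency positive real (epsilon)
#' @param pingpong_gain non-negative real (gamma)
#' @param maternal_transmission real in \[0, 1\]
#' @param te_copy_numbers named non-negative integer vector, TE id -> copies
#' @param reactivity_slope non-negative real (lambda of the reactivity link)
#' @param reactivity_noise_sd non-negative real, percentage points
#' @return object of class `strain_model`
#' @export
strain_model <- function(name, primary_efficiency = 1,
                         pingpong_gain = 1,
                         maternal_transmission = 0.5,
                         te_copy_numbers = integer(0),
                         reactivity_slope = 1e-5,
                         reactivity_noise_sd = 2) {
  assert_scalar_number(primary_efficiency, "primary_efficiency", min = 1e-12)
  assert_scalar_number(pingpong_gain, "pingpong_gain", min = 0)
  assert_scalar_number(maternal_transmission, "maternal_transmission", 0, 1)
  assert_scalar_number(reactivity_slope, "reactivity_slope", min = 0)
  assert_scalar_number(reactivity_noise_sd, "reactivity_noise_sd", min = 0)
  if (length(te_copy_numbers)) {
    if (is.null(names(te_copy_numbers)))
      stop("te_copy_numbers must be named by TE id")
    if (any(te_copy_numbers < 0)) stop("copy numbers must be non-negative")
  }
  structure(list(name = name,
                 primary_efficiency = primary_efficiency,
                 pingpong_gain = pingpong_gain,
                 maternal_transmission = maternal_transmission,
                 te_copy_numbers = te_copy_numbers,
                 reactivity_slope = reactivity_slope,
                 reactivity_noise_sd = reactivity_noise_sd),
            class = "strain_model")
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf(paste0("<strain_model> %s: eps=%.3g gamma=%.3g m=%.3g ",
                     "lambda=%.3g noise=%.3g\n"),
              x$name, x$primary_efficiency, x$pingpong_gain,
              x$maternal_transmission, x$reactivity_slope,
              x$reactivity_noise_sd))
  invisible(x)
}

#' Default copy numbers for the default TE panel
#' @return named integer vector
#' @export
default_copy_numbers <- function() {
  c(I_like = 8L, jockey_like = 20L, copia_like = 12L,
    mdg1_like = 10L, roo_like = 15L, gypsy_like = 18L)
}

#' Default panel of five synthetic strains
#'
#' Two weak strains (high primary efficiency, abundant ancestral-TE piRNAs,
#' low reactivity), one intermediate, and two strong strains, mirroring the
#' weak/strong R-strain dichotomy.
#'
#' @return named list of [strain_model()] objects
#' @export
default_strains <- function() {
  eff <- c(weak1 = 5, weak2 = 4, mid1 = 3, strong1 = 1, strong2 = 0.8)
  lapply(setNames(names(eff), names(eff)), function(nm)
    strain_model(nm, primary_efficiency = eff[[nm]],
                 te_copy_numbers = default_copy_numbers()))
}
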