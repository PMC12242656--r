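#' Molar masses used for unit conversions (g/mol)
#'
#' Glucose 180.16, PHB monomer 86 (C4H6O2), acetate 60.05 (acid form),
#' oxygen 32.
#' @export
molar_masses <- function() {
  c(glucose = 180.16, phb = 86, acetate = 60.05, oxygen = 32)
}

#' Substrate-inhibited uptake kinetics parameters
#'
#' Holds the parameters of the modified Michaelis-Menten glucose-uptake law
#' with substrate inhibition, plus the (constant) maximum oxygen uptake rate
#' used when dissolved oxygen is controlled.
#'
#' @param vmax maximum glucose uptake rate, mmol/gCDW/h.
#' @param K saturation constant for glucose transport, mmol/L.
#' @param Ki glucose inhibition constant, mmol/L; `Inf` disables inhibition.
#' @param vo2max maximum oxygen uptake rate, mmol/gCDW/h (0 for anaerobic
#'   operation).
#' @return object of class `uptake_kinetics`.
#' @export
uptake_kinetics <- function(vmax, K, Ki = Inf, vo2max = 0) {
  stopifnot(vmax > 0, K > 0, Ki > 0, vo2max >= 0)
  structure(list(vmax = vmax, K = K, Ki = Ki, vo2max = vo2max),
            class = "uptake_kinetics")
}

#' Glucose uptake rate at a given concentration
#'
#' Evaluates the substrate-inhibited Michaelis-Menten law
#' \deqn{v(C) = \frac{v_{max} C}{C + K + C^2/K_i}}
#' and returns the positive uptake magnitude; the DFBA layer applies it as a
#' negative lower bound on the glucose exchange flux.  The rate is maximal
#' at \eqn{C = \sqrt{K K_i}} and declines beyond it (substrate inhibition);
#' for \eqn{K_i \to \infty} it reduces to plain Michaelis-Menten kinetics.
#'
#' @param k an [uptake_kinetics()] object.
#' @param C substrate concentration, mmol/L; must be non-negative
#'   (a negative value signals an integrator clamp failure upstream).
#' @return uptake magnitude, mmol/gCDW/h (vectorised over `C`).
#' @export
uptake_rate <- function(k, C) {
  stopifnot(inherits(k, "uptake_kinetics"))
  if (any(C < 0)) stop("negative substrate concentration: ", min(C))
  k$vmax * C / (C + k$K + C^2 / k$Ki)
}

# organism/regime defaults: maximum uptake rates, saturation and inhibition
# constants for the three reference organisms
.kinetic_defaults <- list(
  ecoli = list(
    aerobic = list(vmax = 10.5, K = 0.015, Ki = 8941.7, vo2max = 15),
    anaerobic = list(vmax = 18.5, K = 0.015, Ki = 8941.7, vo2max = 0)
  ),
  cnecator = list(
    aerobic = list(vmax = 3, K = 0.015, Ki = 11139.0, vo2max = 5),
    anaerobic = NULL
  ),
  scerevisiae = list(
    aerobic = list(vmax = 22.5, K = 4.884, Ki = 27102.6, vo2max = 1.5),
    anaerobic = NULL
  )
)

#' Default kinetic parameters per organism and regime
#'
#' Ships the reference parameter set for *E. coli*, *C. necator* and
#' *S. cerevisiae* glucose uptake (substrate-inhibited Michaelis-Menten)
#' and maximum oxygen uptake.  *C. necator* and *S. cerevisiae* have no
#' anaerobic uptake parameters (neither grows anaerobically in the
#' corresponding reconstructions), so requesting those combinations is an
#' error.  A YAML configuration file (or an equivalent named list) can
#' override any field.
#'
#' @param organism `"ecoli"`, `"cnecator"`, or `"scerevisiae"`.
#' @param regime `"aerobic"` or `"anaerobic"`.
#' @param config optional YAML file path or named list overriding any of
#'   `vmax`, `K`, `Ki`, `vo2max`.
#' @return an [uptake_kinetics()] object.
#' @export
default_parameters <- function(organism = c("ecoli", "cnecator",
                                            "scerevisiae"),
                               regime = c("aerobic", "anaerobic"),
                               config = NULL) {
  organism <- match.arg(organism)
  regime <- match.arg(regime)
  p <- .kinetic_defaults[[organism]][[regime]]
  if (is.null(p)) {
    stop("no ", regime, " uptake parameters are defined for '", organism,
         "' (anaerobic growth is not available for this organism)")
  }
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    unknown <- setdiff(names(config), c("vmax", "K", "Ki", "vo2max"))
    if (length(unknown)) {
      stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(config)] <- config
  }
  uptake_kinetics(vmax = p$vmax, K = p$K, Ki = p$Ki, vo2max = p$vo2max)
}
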