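#' Glucose control model parameters
#'
#' Constructs the nine-parameter vector of the delay-differential glucose
#' control model. Defaults are the literature-optimized population values:
#'
#' \describe{
#'   \item{kxgi}{Rate of glucose uptake by insulin-dependent tissues,
#'     1/(min * pM). Default 3.11e-5.}
#'   \item{tgh}{Net hepatic glucose output minus insulin-independent zero-order
#'     uptake, mmol/(min * kgBW). Default 0.003.}
#'   \item{vg}{Apparent glucose distribution volume, l/kgBW. Default 0.187.}
#'   \item{kxi}{First-order insulin disappearance rate, 1/min. Default
#'     1.211e-2.}
#'   \item{tigmax}{Maximal rate of second-phase insulin release,
#'     pmol/(min * kgBW). Default 0.1.}
#'   \item{vi}{Apparent insulin distribution volume, l/kgBW. Default 0.236.}
#'   \item{tau_g}{Pancreatic response delay, min. Default 24.}
#'   \item{g_star}{Glycaemia at which insulin release is half-maximal, mmol/l.
#'     Default 9.}
#'   \item{gamma}{Progressivity of the pancreatic response (dimensionless).
#'     Default 3.205.}
#' }
#'
#' @param kxgi,tgh,vg,kxi,tigmax,vi,tau_g,g_star,gamma model parameters, see
#'   Details. All must be positive.
#' @return A named numeric vector of class `"glycemia_params"`.
#' @examples
#' p <- glycemia_params()
#' p["kxgi"]
#' @export
glycemia_params <- function(kxgi = 3.11e-5, tgh = 0.003, vg = 0.187,
                            kxi = 1.211e-2, tigmax = 0.1, vi = 0.236,
                            tau_g = 24, g_star = 9, gamma = 3.205) {
  p <- c(kxgi = kxgi, tgh = tgh, vg = vg, kxi = kxi, tigmax = tigmax,
         vi = vi, tau_g = tau_g, g_star = g_star, gamma = gamma)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all glycemia parameters must be positive and finite")
  if (gamma <= 1) stop("gamma must exceed 1")
  structure(p, class = "glycemia_params")
}

#' @export
print.glycemia_params <- function(x, ...) {
  cat("Glucose control model parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Names of the trainable glycemia parameters, in canonical order
#' @return Character vector of the nine parameter names.
#' @export
glycemia_param_names <- function() {
  c("kxgi", "tgh", "vg", "kxi", "tigmax", "vi", "tau_g", "g_star", "gamma")
}

#' Digestion model parameters
#'
#' First-order mass-balance rates of the two-compartment digestion model.
#' These are population-level constants (digestion is assumed unaffected by
#' diabetes) and are never trained.
#'
#' @param kge basal gastric emptying rate, 1/min.
#' @param khyd_ref starch hydrolysis rate at glycemic index 1, 1/min.
#' @param kabs intestinal monosaccharide absorption rate, 1/min.
#' @param c_lipid,c_protein,c_fiber dimensionless gastric-emptying retardation
#'   per gram of lipid / protein / fiber currently in the stomach.
#' @return A named numeric vector of class `"absorption_params"`.
#' @export
absorption_params <- function(kge = 0.028, khyd_ref = 0.023, kabs = 0.023,
                              c_lipid = 0.02, c_protein = 0.02,
                              c_fiber = 0.05) {
  p <- c(kge = kge, khyd_ref = khyd_ref, kabs = kabs, c_lipid = c_lipid,
         c_protein = c_protein, c_fiber = c_fiber)
  if (any(!is.finite(p)) || any(p[1:3] <= 0) || any(p[4:6] < 0))
    stop("rates must be positive, retardation coefficients non-negative")
  structure(p, class = "absorption_params")
}

#' Endogenous insulin release fraction
#'
#' The sigmoidal pancreatic response \eqn{f(G) = (G/G^*)^\gamma / (1 +
#' (G/G^*)^\gamma)}: the fraction of maximal second-phase insulin release at
#' glycaemia `g`. \eqn{f(0) = 0}, \eqn{f(G^*) = 1/2}, \eqn{f \to 1} as
#' \eqn{G \to \infty}, strictly increasing.
#'
#' @param g glycaemia, mmol/l (vectorized, must be >= 0).
#' @param g_star half-maximal glycaemia, mmol/l.
#' @param gamma progressivity exponent.
#' @return Release fraction in `[0, 1)`.
#' @examples
#' endogenous_release_fraction(9)       # exactly 0.5
#' endogenous_release_fraction(18)
#' @export
endogenous_release_fraction <- function(g, g_star = 9, gamma = 3.205) {
  if (any(g < 0)) stop("glycaemia must be non-negative")
  r <- (g / g_star)^gamma
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Basal steady state of the glucose control model
#'
#' Solves the algebraic system obtained by zeroing the glucose and insulin
#' balances with no meals and no exogenous insulin:
#' \eqn{0 = -K_{xgi} G I + T_{GH}/V_G} and
#' \eqn{0 = -K_{xi} I + (T_{iGmax}/V_I) f(G)}.
#' The root in G is unique because the first equation makes I a decreasing
#' function of G while the pancreatic response is increasing.
#'
#' @param params a [glycemia_params()] vector.
#' @return Named numeric `c(G = , I = )` in mmol/l and pM.
#' @export
steady_state <- function(params = glycemia_params()) {
  p <- as.numeric(params)
  names(p) <- names(params)
  i_of_g <- function(g) p["tgh"] / (p["vg"] * p["kxgi"] * g)
  bal <- function(g) {
    (p["tigmax"] / p["vi"]) *
      endogenous_release_fraction(g, p["g_star"], p["gamma"]) -
      p["kxi"] * i_of_g(g)
  }
  # the balance is negative as G -> 0 and approaches a positive constant as
  # G grows; expand the bracket until it straddles the root (degenerate
  # parameter draws can push the steady state very high)
  hi <- 1e3
  while (bal(hi) < 0 && hi < 1e15) hi <- hi * 10
  g <- uniroot(bal, c(1e-3, hi), tol = 1e-12)$root
  c(G = g, I = unname(i_of_g(g)))
}
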