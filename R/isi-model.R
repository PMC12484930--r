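#' Renewal interspike-interval model in operational time
#'
#' The operational-time ISI density g() has mean fixed at mu_g = 1 s, so the
#' renewal process in operational time fires at 1 Hz and its irregularity is
#' set entirely by the shape of g(). We parameterize g() by
#' phi = sigma_g^2 / mu_g^2, the squared coefficient of variation: phi = 1 is
#' Poisson, phi < 1 sub-Poisson (regular), phi > 1 super-Poisson (bursty).
#' For the gamma family the shape is k = 1/phi and scale theta = phi, so that
#' k * theta = 1 and k * theta^2 = phi; the third central moment is
#' psi(phi) = 2 phi^2. `family = "exponential"` is the phi = 1 gamma case.
#'
#' @param phi Spiking irregularity, > 0.
#' @param family `"gamma"` (default) or `"exponential"`.
#' @return An object of class `isi_model` with elements `family`, `phi`,
#'   `mu_g` (always 1).
#' @export
isi_model <- function(phi = 1, family = c("gamma", "exponential")) {
  family <- match.arg(family)
  stop_if_not(is.numeric(phi) && length(phi) == 1 && phi > 0,
              "phi must be a single positive number")
  if (family == "exponential") {
    stop_if_not(isTRUE(all.equal(phi, 1)),
                "exponential family requires phi = 1")
    phi <- 1
  }
  structure(list(family = family, phi = phi, mu_g = 1),
            class = "isi_model")
}

#' @export
print.isi_model <- function(x, ...) {
  cat(sprintf("<isi_model> %s, phi = %.4g (mu_g = 1 s)\n", x$family, x$phi))
  invisible(x)
}

# Third central moment of g() as a function of phi (gamma family).
psi_gamma <- function(phi) 2 * phi^2

#' Asymptotic spike-count moments of a stationary renewal process
#'
#' For an equilibrium renewal process with ISI moments mu, sigma^2, mu_3,
#' the count in a bin of size T has mean `T / mu` and variance
#' `sigma^2 T / mu^3 + sigma^4 / (2 mu^4) + 1/6 - mu_3 / (3 mu^3) + O(1/T)`.
#' With the gamma parameterization (mu = 1, sigma^2 = phi, mu_3 = 2 phi^2)
#' this reduces to `phi * T + 1/6 - phi^2 / 6`. At phi = 1 the constant
#' corrections cancel (1/2 + 1/6 - 2/3 = 0), recovering the Poisson identity
#' variance = mean = T.
#'
#' @param model An [isi_model].
#' @param T_bin Bin size in operational seconds, > 0.
#' @return Named list with `mean` and `variance` of the count.
#' @export
renewal_count_moments <- function(model, T_bin) {
  stop_if_not(inherits(model, "isi_model"), "model must be an isi_model")
  stop_if_not(T_bin > 0, "bin size must be positive")
  phi <- model$phi
  list(mean = T_bin,
       variance = phi * T_bin + phi^2 / 2 + 1 / 6 - psi_gamma(phi) / 3)
}

# i.i.d. operational-time ISIs from g().
draw_isis <- function(model, n) {
  if (n == 0) return(numeric(0))
  x <- if (model$family == "exponential" || model$phi == 1) {
    rexp(n, rate = 1)
  } else {
    rgamma(n, shape = 1 / model$phi, scale = model$phi)
  }
  # floor degenerate zero draws (tiny phi) to preserve strict ordering
  pmax(x, 1e-9)
}
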