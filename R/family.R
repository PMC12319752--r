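# Response-family abstraction for the distributional engine.
#
# A family bundles density/CDF/quantile functions in the four-parameter
# (mu, sigma, nu, tau) parameterisation together with analytic scores on
# the linear-predictor (eta) scale. Links are fixed: identity for mu and
# nu, log for sigma and tau.

#' Distribution families for normative models
#'
#' Returns the family object used by \code{\link{fit_normative}}.
#'
#' \describe{
#'   \item{\code{"shash"}}{Sinh-arcsinh location-scale family (Jones &
#'     Pewsey). With \eqn{z = (y-\mu)/\sigma},
#'     \eqn{Z = \sinh(\tau \, \mathrm{asinh}(z) - \nu)} is standard
#'     normal, so centiles are available in closed form through the
#'     normal CDF. \eqn{\nu} controls skew (0 = symmetric) and
#'     \eqn{\tau > 0} tail weight (1 = normal); at \eqn{\nu = 0,
#'     \tau = 1} the family reduces exactly to the Gaussian.}
#'   \item{\code{"normal"}}{Gaussian family; \eqn{\nu, \tau} are held at
#'     their neutral values and only location and scale are modelled.}
#' }
#'
#' @param name \code{"shash"} or \code{"normal"}.
#' @return A list of class \code{"bn_family"} with elements \code{name},
#'   \code{free} (which parameters are fitted), \code{neutral} (fixed
#'   values of the others), and functions \code{dfun}, \code{pfun},
#'   \code{qfun}, \code{rfun}, \code{score}.
#' @export
bn_family <- function(name = c("shash", "normal")) {
  name <- match.arg(name)
  fam <- switch(name, shash = shash_family(), normal = normal_family())
  structure(fam, class = "bn_family")
}

# clamp the argument of sinh/cosh to avoid overflow
.clamp_w <- function(w) pmin(pmax(w, -300), 300)

shash_family <- function() {
  trans <- function(y, mu, sigma, nu, tau) {
    z <- (y - mu) / sigma
    r <- asinh(z)
    w <- .clamp_w(tau * r - nu)
    list(z = z, r = r, w = w, S = sinh(w), C = cosh(w))
  }
  dfun <- function(y, mu, sigma, nu, tau, log = FALSE) {
    t <- trans(y, mu, sigma, nu, tau)
    ll <- -0.5 * log(2 * pi) + log(tau) + log(t$C) - log(sigma) -
      0.5 * log1p(t$z^2) - 0.5 * t$S^2
    if (log) ll else exp(ll)
  }
  pfun <- function(y, mu, sigma, nu, tau) {
    t <- trans(y, mu, sigma, nu, tau)
    pnorm(t$S)
  }
  qfun <- function(p, mu, sigma, nu, tau) {
    mu + sigma * sinh((asinh(qnorm(p)) + nu) / tau)
  }
  rfun <- function(n, mu, sigma, nu, tau) {
    qfun(runif(n), mu, sigma, nu, tau)
  }
  # standardised mean E[(Y - mu)/sigma] = E[sinh((asinh(Z) + nu)/tau)],
  # Z standard normal; numerical quadrature, vectorised over (nu, tau)
  zg <- seq(-8, 8, length.out = 401)
  ag <- asinh(zg)
  wg <- dnorm(zg); wg <- wg / sum(wg)
  meanz <- function(nu, tau) {
    arg <- outer(nu, ag, "+") / tau
    drop(sinh(arg) %*% wg)
  }
  # standardised SD of (Y - mu)/sigma under the family
  sdz <- function(nu, tau) {
    arg <- outer(nu, ag, "+") / tau
    s <- sinh(arg)
    m1 <- drop(s %*% wg)
    m2 <- drop(s^2 %*% wg)
    sqrt(pmax(m2 - m1^2, 1e-12))
  }
  # dl/deta for one parameter; eta scale absorbs the log links
  score <- function(y, mu, sigma, nu, tau, par) {
    t <- trans(y, mu, sigma, nu, tau)
    g <- tanh(t$w) - t$S * t$C          # dl/dw
    sq <- sqrt(1 + t$z^2)
    switch(par,
      mu = -g * tau / (sigma * sq) + t$z / (sigma * (1 + t$z^2)),
      sigma = -1 + t$z^2 / (1 + t$z^2) - g * tau * t$z / sq,
      nu = -g,
      tau = 1 + tau * g * t$r)
  }
  list(name = "shash",
       free = c("mu", "sigma", "nu", "tau"),
       neutral = c(nu = 0, tau = 1),
       dfun = dfun, pfun = pfun, qfun = qfun, rfun = rfun,
       meanz = meanz, sdz = sdz, score = score)
}

normal_family <- function() {
  list(name = "normal",
       free = c("mu", "sigma"),
       neutral = c(nu = 0, tau = 1),
       dfun = function(y, mu, sigma, nu, tau, log = FALSE)
         dnorm(y, mu, sigma, log = log),
       pfun = function(y, mu, sigma, nu, tau) pnorm(y, mu, sigma),
       qfun = function(p, mu, sigma, nu, tau) qnorm(p, mu, sigma),
       rfun = function(n, mu, sigma, nu, tau) rnorm(n, mu, sigma),
       meanz = function(nu, tau) rep(0, length(nu)),
       sdz = function(nu, tau) rep(1, length(nu)),
       score = function(y, mu, sigma, nu, tau, par) {
         z <- (y - mu) / sigma
         switch(par, mu = z / sigma, sigma = z^2 - 1,
                nu = rep(0, length(y)), tau = rep(0, length(y)))
       })
}

# total log-likelihood under a family
family_loglik <- function(fam, y, mu, sigma, nu, tau) {
  sum(fam$dfun(y, mu, sigma, nu, tau, log = TRUE))
}
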