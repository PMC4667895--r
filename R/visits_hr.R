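#' Visit rate versus home range size: random-intercept model family
#'
#' Fits, by direct maximum likelihood, eight Gaussian random-intercept
#' models of the log mean number of visits per location (log n-tilde)
#' against log home-range size (log A) and season, with the individual
#' as the random-effect grouping factor:
#'
#' \describe{
#'   \item{R1}{\eqn{\log \tilde n = a_0^{season} + a_1^{season}\log A}}
#'   \item{R2}{\eqn{\log \tilde n = a_0 + a_1^{season}\log A}}
#'   \item{R3}{\eqn{\log \tilde n = a_0^{season} + a_1\log A}}
#'   \item{R4}{\eqn{\log \tilde n = a_0^{season} - \log A} (offset slope -1)}
#'   \item{R5}{\eqn{\log \tilde n = a_0^{season}}}
#'   \item{R6}{\eqn{\log \tilde n = a_0 + a_1\log A}}
#'   \item{R7}{\eqn{\log \tilde n = a_0 - \log A}}
#'   \item{R8}{\eqn{\log \tilde n = a_0}}
#' }
#'
#' The motivating premise: if locations were spread uniformly, the mean
#' number of visits per location would be inversely proportional to home
#' range size, i.e. a log-log slope of exactly -1 — the offset models R4
#' and R7 encode that proportionality. Each model's parameter count df
#' includes the random-intercept and residual variances (R1: 6 ... R8:
#' 3), and models are ranked by the small-sample corrected criterion
#' AICc = AIC + 2 df (df + 1) / (n - df - 1).
#'
#' @param rows data.frame with columns `animal_id`, `season`,
#'   `mean_visits` (n-tilde, > 0) and `area_km2` (A, > 0), one row per
#'   animal-season.
#' @return object of class `visits_hr_scan`: list with `fits`
#'   (data.frame: model, df, logL, AIC, AICc, sigma2, tau2), `coefs`
#'   (named list of fixed-coefficient vectors) and `best`.
#' @export
fit_visits_vs_hr <- function(rows) {
  need <- c("animal_id", "season", "mean_visits", "area_km2")
  if (!all(need %in% names(rows)))
    stop("`rows` must have columns: ", paste(need, collapse = ", "))
  if (nrow(rows) < 4L) stop("need at least 4 animal-season rows")
  if (any(rows$mean_visits <= 0) || any(rows$area_km2 <= 0))
    stop("`mean_visits` and `area_km2` must be positive")
  y <- log(rows$mean_visits)
  logA <- log(rows$area_km2)
  season <- factor(rows$season)
  animal <- factor(rows$animal_id)
  n <- length(y)

  designs <- list(
    R1 = list(X = stats::model.matrix(~ 0 + season + season:logA),
              offset = 0),
    R2 = list(X = stats::model.matrix(~ 1 + season:logA), offset = 0),
    R3 = list(X = stats::model.matrix(~ 0 + season + logA), offset = 0),
    R4 = list(X = stats::model.matrix(~ 0 + season), offset = -logA),
    R5 = list(X = stats::model.matrix(~ 0 + season), offset = 0),
    R6 = list(X = stats::model.matrix(~ 1 + logA), offset = 0),
    R7 = list(X = stats::model.matrix(~ 1, data.frame(y)), offset = -logA),
    R8 = list(X = stats::model.matrix(~ 1, data.frame(y)), offset = 0))

  fits <- list(); coefs <- list()
  for (m in names(designs)) {
    d <- designs[[m]]
    f <- .ml_random_intercept(y - d$offset, d$X, animal)
    df <- ncol(d$X) + 2L
    aic <- -2 * f$logL + 2 * df
    aicc <- if (n - df - 1 > 0) aic + 2 * df * (df + 1) / (n - df - 1)
            else Inf
    fits[[m]] <- data.frame(model = m, df = df, logL = f$logL, AIC = aic,
                            AICc = aicc, sigma2 = f$sigma2, tau2 = f$tau2)
    coefs[[m]] <- f$beta
  }
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  best <- fits[order(fits$AICc, fits$df), , drop = FALSE][1, , drop = FALSE]
  structure(list(fits = fits, coefs = coefs, best = best,
                 data = data.frame(animal_id = animal, season = season,
                                   log_n = y, log_A = logA)),
            class = "visits_hr_scan")
}

# direct ML for y ~ N(X beta, sigma2 I + tau2 Z Z'), Z = group indicator.
# profile over beta (GLS), optimize the two log-variances; variances are
# floored at 1e-8 (ridge) so degenerate data yield a finite fit.
.ml_random_intercept <- function(y, X, group) {
  Z <- stats::model.matrix(~ 0 + group)
  n <- length(y)
  nll <- function(par) {
    s2 <- exp(par[1]); t2 <- exp(par[2])
    V <- s2 * diag(n) + t2 * tcrossprod(Z)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Xi <- backsolve(R, X, transpose = TRUE)
    yi <- backsolve(R, y, transpose = TRUE)
    beta <- tryCatch(qr.solve(Xi, yi), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    r <- yi - Xi %*% beta
    0.5 * (2 * sum(log(diag(R))) + sum(r^2) + n * log(2 * pi))
  }
  v0 <- stats::var(y)
  if (!is.finite(v0) || v0 <= 0) v0 <- 1e-4
  best <- NULL
  for (init in list(c(log(v0), log(v0 / 2)), c(log(v0), log(1e-6)),
                    c(log(1e-6), log(v0)))) {
    o <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = log(1e-8), upper = log(1e8))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s2 <- exp(best$par[1]); t2 <- exp(best$par[2])
  V <- s2 * diag(n) + t2 * tcrossprod(Z)
  R <- chol(V)
  Xi <- backsolve(R, X, transpose = TRUE)
  yi <- backsolve(R, y, transpose = TRUE)
  beta <- qr.solve(Xi, yi)
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       sigma2 = s2, tau2 = t2, logL = -best$value)
}

#' @export
print.visits_hr_scan <- function(x, ...) {
  cat("<visits_hr_scan> models ranked by AICc:\n")
  tab <- x$fits[order(x$fits$AICc), c("model", "df", "AICc")]
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.visits_hr_scan <- function(object, model = object$best$model, ...) {
  object$coefs[[model]]
}
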