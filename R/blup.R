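#' BLUP of a replicated trait under a two-random-effect model
#'
#' Fits \eqn{y_{ir} = \mu + u_i + r_r + e_{ir}} by REML, with
#' independent Gaussian sample effects \eqn{u_i \sim N(0,
#' \sigma^2_{sample})}, replicate effects \eqn{r_r \sim N(0,
#' \sigma^2_{rep})} and residuals, via \code{lme4::lmer(content ~
#' (1|sample) + (1|rep))}.  The reported per-sample value is \eqn{\mu +
#' \hat u_i} (not the centered BLUP) so downstream statistics stay on
#' the measurement scale.
#'
#' Degenerate inputs are handled explicitly: a constant response yields
#' all variance components 0 and every BLUP equal to that constant; a
#' single replicate level drops the replicate term with a warning and
#' fixes \eqn{\sigma^2_{rep} = 0}.
#'
#' @param traits \code{data.frame} with columns \code{sample},
#'   \code{rep}, \code{content} (one row per measurement).
#' @return A \linkS4class{BlupFit}.
#' @examples
#' tr <- data.frame(sample = rep(c("a", "b"), each = 3),
#'                  rep = rep(1:3, 2),
#'                  content = c(0.5, 0.6, 0.55, 0.9, 1.0, 0.95))
#' fit <- fitBlup(tr)
#' blup(fit)
#' @export
fitBlup <- function(traits) {
    stopifnot(all(c("sample", "rep", "content") %in% names(traits)))
    traits$sample <- as.character(traits$sample)
    ids <- unique(traits$sample)
    if (length(ids) < 2L) stop("need >= 2 samples")
    mu0 <- mean(traits$content)
    if (var(traits$content) == 0) {
        return(methods::new("BlupFit",
                            blup = setNames(rep(mu0, length(ids)), ids),
                            varcomp = c(sample = 0, rep = 0, residual = 0),
                            mu = mu0, converged = TRUE))
    }
    dropRep <- length(unique(traits$rep)) < 2L
    if (dropRep)
        warning("single replicate level: sigma2_rep fixed at 0")
    form <- if (dropRep) content ~ (1 | sample) else
        content ~ (1 | sample) + (1 | rep)
    fit <- suppressMessages(
        lme4::lmer(form, data = traits, REML = TRUE,
                   control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       calc.derivs = FALSE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getvc <- function(g) {
        v <- vc$vcov[vc$grp == g]
        if (length(v)) v else 0
    }
    mu <- as.numeric(lme4::fixef(fit)[1L])
    re <- lme4::ranef(fit)$sample
    b <- setNames(mu + re[[1L]], rownames(re))
    b <- b[ids]
    conv <- length(fit@optinfo$conv$lme4) == 0L
    if (!conv) warning("REML optimizer reported convergence issues")
    methods::new("BlupFit", blup = b,
                 varcomp = c(sample = getvc("sample"),
                             rep = getvc("rep"),
                             residual = getvc("Residual")),
                 mu = mu, converged = conv)
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests the values against a normal distribution with mean and SD
#' estimated from the data, \eqn{D = \sup_x |F_n(x) - \Phi((x - \bar
#' x)/s)|}, with the asymptotic p-value.  Because the parameters are
#' estimated, the test is conservative (no Lilliefors correction); the
#' returned object flags this.
#'
#' @param values Numeric vector, \eqn{n \ge 8}.
#' @return List with \code{D}, \code{p}, and
#'   \code{parametersEstimated = TRUE}.
#' @export
ksNormality <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) < 8L) stop("need n >= 8")
    s <- sd(values)
    if (s == 0) stop("zero variance: K-S test undefined")
    kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), s))
    list(D = unname(kt$statistic), p = kt$p.value,
         parametersEstimated = TRUE)
}
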