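# Shared fixtures and independent oracles for the test suite.

makeData <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                     ids = sprintf("rs%d", seq_along(bx)), ...) {
  MRData(ids, bx, sx, by, sy, ...)
}

# homogeneous dataset: every variant has exactly ratio theta
homogeneousData <- function(theta, J = 5, bx = NULL, sy = NULL) {
  if (is.null(bx)) bx <- seq(0.05, 0.05 + 0.02 * (J - 1), length.out = J)
  J <- length(bx)
  if (is.null(sy)) sy <- rep(0.02, J)
  makeData(bx, theta * bx, sy)
}

randomData <- function(J, seed, sy = NULL) {
  set.seed(seed)
  bx <- runif(J, 0.03, 0.15)
  if (is.null(sy)) sy <- runif(J, 0.01, 0.05)
  by <- 0.3 * bx + rnorm(J, 0, sy)
  makeData(bx, by, sy)
}

writeAssocTable <- function(df, path = tempfile(fileext = ".tsv"),
                            sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

assocRow <- function(rsid, ea, oa, eaf, beta, se, pvalue = 0.001) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue, stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# IVW through lm(): a different code path from the closed-form sums
oracleIVW <- function(d) {
  fit <- lm(betaOutcome(d) ~ betaExposure(d) - 1,
            weights = 1 / seOutcome(d)^2)
  sm <- summary(fit)
  list(theta = unname(coef(fit)[1]),
       seFixed = unname(sm$coefficients[1, 2]) / sm$sigma)
}

# Egger slope/intercept through lm() with weights
oracleEgger <- function(d) {
  d <- orientPositive(d)
  fit <- lm(betaOutcome(d) ~ betaExposure(d), weights = 1 / seOutcome(d)^2)
  unname(coef(fit))  # c(intercept, slope)
}

# Cochran's Q by its definitional sum over the ratio estimates
oracleQ <- function(d) {
  th <- betaOutcome(d) / betaExposure(d)
  se <- seOutcome(d) / abs(betaExposure(d))
  w <- 1 / se^2
  thetaHat <- sum(w * th) / sum(w)
  sum(w * (th - thetaHat)^2)
}

# mode of the weighted kernel density by brute-force dense grid summation
oracleMode <- function(th, w, phi = 1) {
  w <- w / sum(w)
  wmed <- function(x, wt) {
    o <- order(x); x <- x[o]; wt <- wt[o] / sum(wt)
    s <- cumsum(wt) - wt / 2
    if (0.5 <= s[1]) return(x[1])
    if (0.5 >= s[length(x)]) return(x[length(x)])
    approx(s, x, xout = 0.5, ties = "ordered")$y
  }
  mu <- sum(w * th)
  sdw <- sqrt(sum(w * (th - mu)^2))
  madw <- 1.4826 * wmed(abs(th - wmed(th, w)), w)
  s <- min(sdw, madw); if (s <= 0) s <- max(sdw, madw)
  h <- phi * 0.9 * s * length(th)^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 20001)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, th, h)), numeric(1))
  grid[which.max(dens)]
}
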