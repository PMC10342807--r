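# Independent oracles and small fixture builders shared across tests.

# Exhaustive hypergeometric enumeration of the one-sided Fisher tails for a
# 2x2 table, from first principles (log binomial coefficients), independent
# of stats::phyper / fisher.test.
enum_fisher <- function(UU, UD, DU, DD, alternative = "anti") {
  rowU <- UU + UD
  colU <- UU + DU
  N <- UU + UD + DU + DD
  lo <- max(0L, rowU + colU - N)
  hi <- min(rowU, colU)
  xs <- lo:hi
  logp <- lchoose(colU, xs) + lchoose(N - colU, rowU - xs) -
    lchoose(N, rowU)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  if (alternative == "anti") sum(p[xs <= UU]) else sum(p[xs >= UU])
}

# Brute-force contingency counting between two named Z vectors, written
# independently of contingency().
brute_contingency <- function(za, zb, thr = 2) {
  shared <- intersect(names(za), names(zb))
  a <- za[shared]; b <- zb[shared]
  keep <- abs(a) > thr & abs(b) > thr
  a <- a[keep]; b <- b[keep]
  c(UU = sum(a > 0 & b > 0), UD = sum(a > 0 & b < 0),
    DU = sum(a < 0 & b > 0), DD = sum(a < 0 & b < 0))
}

# Per-gene two-covariate OLS through lm(), the slow reference for the
# vectorised differential profile.
lm_oracle_z <- function(study) {
  tr <- as.numeric(study$annotations$treatment == "treated")
  sx <- as.numeric(study$annotations$sex == "F")
  apply(study$values, 1, function(y) {
    fit <- summary(stats::lm(y ~ tr + sx))
    fit$coefficients["tr", "t value"]
  })
}

# Central finite-difference gradient of the layout stress wrt the angles.
fd_stress_gradient <- function(r, theta, d, model, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    (stress(list(radius = r, theta = up), model) -
       stress(list(radius = r, theta = dn), model)) / (2 * h)
  }, numeric(1))
}

# A small standard-normal null profile with deterministic content.
null_profile <- function(n = 1000, seed = 1, name = "null") {
  withr::with_seed(seed, gene_profile(
    stats::setNames(stats::rnorm(n), sprintf("G%05d", seq_len(n))),
    name = name))
}

# Tiny expression study built by hand (values chosen, not simulated).
toy_study <- function() {
  vals <- matrix(as.numeric(1:12), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("s1", "s2", "s3", "s4")))
  ann <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    treatment = c("treated", "treated", "control",
                                  "control"),
                    sex = c("F", "M", "F", "M"),
                    stringsAsFactors = FALSE)
  expression_study(vals, ann)
}
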