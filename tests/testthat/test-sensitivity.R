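# LHS sampling, relevance filters, PRCC and OFAT measures.

test_that("LHS columns are stratified, bounded and reproducible", {
  rng <- parameter_ranges("clinical")
  s1 <- lhs_sample(rng, 40, seed = 5)
  s2 <- lhs_sample(rng, 40, seed = 5)
  s3 <- lhs_sample(rng, 40, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  # stratification: one point per stratum in normalized coordinates
  for (j in seq_len(nrow(rng))) {
    if (rng$integer[j]) next
    u <- (s1[[rng$parameter[j]]] - rng$min[j]) / (rng$max[j] - rng$min[j])
    expect_setequal(findInterval(sort(u), seq(0, 1, length.out = 41),
                                 rightmost.closed = TRUE), 1:40)
  }
  # integer column stays integer and in range
  nl <- s1$N_LIMP
  expect_true(all(nl == round(nl) & nl >= 8 & nl <= 24))
  expect_error(lhs_sample(rng, 1, seed = 1), ">= 2")
})

test_that("LHS marginals are uniform (chi-square goodness of fit)", {
  s <- lhs_sample(parameter_ranges("sensitivity"), 5000, seed = 2)
  for (col in c("T_C_stem", "P_sym", "R_A")) {
    rng <- parameter_ranges("sensitivity")
    r <- rng[rng$parameter == col, ]
    u <- (s[[col]] - r$min) / (r$max - r$min)
    counts <- table(cut(u, seq(0, 1, by = 0.1)))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("filters agree with brute-force per-row predicates", {
  smp <- lhs_sample(parameter_ranges("sensitivity"), 200, seed = 9)
  mask <- apply_filters(smp, "sensitivity")
  brute <- vapply(seq_len(200), function(i) {
    b <- tryCatch(balanced_composition(sample_row_params(smp[i, ])),
                  error = function(e) NULL)
    !is.null(b) && !b$negative_growth && b$T_d >= 26 && b$SF <= 1e-3
  }, logical(1))
  expect_equal(mask$keep, brute)
  expect_true(all(is.na(mask$reason[mask$keep])))
  expect_true(all(!is.na(mask$reason[!mask$keep])))
  # reason codes name the rule that fired
  neg <- mask$reason[!mask$keep & !is.na(mask$T_d) & mask$T_d < 0]
  expect_true(all(neg == "negative growth"))
})

test_that("clinical preset enforces the tighter relevance rules", {
  smp <- build_subtype_sample("SCC", 150, seed = 3)
  tab <- smp$table[smp$mask$keep, ]
  expect_true(all(tab$T_A <= 24 & tab$T_N <= 200 & tab$R_NDiff <= 0.02))
  expect_true(all(tab$P_sleep >= 0 & tab$P_sleep <= 1))
  # filter idempotence: survivors pass a second filtering untouched
  again <- apply_filters(tab, "clinical", profile = smp$profile)
  expect_true(all(again$keep))
  # each survivor reproduces the subtype growth fraction
  for (p in smp$params[seq_len(min(5, length(smp$params)))]) {
    expect_equal(balanced_composition(p)$GF, 0.36, tolerance = 1e-3)
  }
})

test_that("PRCC detects a monotone dependence and nothing else", {
  set.seed(42)
  n <- 500
  X <- tibble::tibble(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- exp(3 * X$x1)                 # nonlinear but monotone in x1 only
  res <- prcc(X, y)
  expect_gt(res$prcc[res$parameter == "x1"], 0.95)
  expect_true(all(abs(res$prcc[res$parameter != "x1"]) < 0.15))
  expect_true(res$significant[res$parameter == "x1"])
})

test_that("PRCC equals partial correlation of rank-space residuals", {
  set.seed(7)
  n <- 120
  X <- tibble::tibble(a = runif(n), b = runif(n), c = runif(n))
  y <- X$a - 2 * X$b + 0.5 * rnorm(n)
  res <- prcc(X, y)
  # independent oracle: lm residuals on the rank-transformed data
  R <- as.data.frame(apply(cbind(X, y = y), 2, rank))
  for (v in c("a", "b", "c")) {
    ctrl <- setdiff(c("a", "b", "c"), v)
    f1 <- stats::lm(stats::reformulate(ctrl, v), data = R)
    f2 <- stats::lm(stats::reformulate(ctrl, "y"), data = R)
    oracle <- stats::cor(stats::resid(f1), stats::resid(f2))
    expect_equal(res$prcc[res$parameter == v], oracle, tolerance = 1e-10)
  }
})

test_that("PRCC is invariant under monotone transforms and bounded", {
  set.seed(13)
  n <- 200
  X <- tibble::tibble(u = runif(n), v = runif(n))
  y <- X$u + X$v + 0.2 * rnorm(n)
  r1 <- prcc(X, y)
  X2 <- dplyr::mutate(X, u = exp(5 * u))      # strictly monotone transform
  r2 <- prcc(X2, y)
  expect_equal(r1$prcc, r2$prcc, tolerance = 1e-12)
  expect_true(all(abs(r1$prcc) <= 1))
  # collinear controls are refused with the offending columns named
  X3 <- dplyr::mutate(X, w = u)
  expect_error(prcc(X3, y), "collinear.*[uw]")
})

test_that("OFAT measures reproduce closed-form elasticities", {
  # fake evaluator reading one parameter; linear map has elasticity 1
  lin <- function(p) 3 * p$T_A
  base <- toy_params()
  m <- ofat_measures(lin, base, "T_A", delta = 0.10)
  expect_equal(m$sm_plus, 1, tolerance = 1e-9)
  expect_equal(m$sm_minus, 1, tolerance = 1e-9)
  cst <- function(p) 42
  m0 <- ofat_measures(cst, base, "T_A")
  expect_equal(c(m0$sm_plus, m0$sm_minus), c(0, 0))
  # quadratic at p = 2, +10%: ((4.84 - 4)/4)/0.10 = 2.1
  sq <- function(p) p$T_C_stem^2
  base2 <- toy_params(T_C = 2)
  m2 <- ofat_measures(sq, base2, "T_C_stem", delta = 0.10)
  expect_equal(m2$sm_plus, 2.1, tolerance = 1e-9)
  expect_equal(m2$sm_minus, 1.9, tolerance = 1e-9)
  # failed evaluations are flagged, not propagated
  boom <- function(p) if (p$T_A > 5) stop("nope") else 1
  mf <- ofat_measures(boom, base, "T_A", ckr_base = 1)
  expect_true(mf$failed)
})

test_that("the variability weight scales the OFAT score as defined", {
  expect_equal(ofat_score(1, -1, 0, 1), 2)
  expect_equal(ofat_score(0.5, 0.5, 0, 1), 0)        # antisymmetric cancel
  expect_equal(ofat_score(1, -1, 1, 3), 1 * (2 / 2)) # range 2, mean 2
  # doubling the range at fixed mean doubles the score
  expect_equal(ofat_score(1, -1, 0.5, 3.5) / ofat_score(1, -1, 1.25, 2.75), 2)
  expect_error(ofat_score(1, -1, -1, 1), "zero mean")
})

test_that("integer parameters use the actually applied change", {
  val <- function(p) p$N_LIMP * 2
  base <- baseline_params("SCC")     # N_LIMP = 22; +10% -> 24.2 -> 24
  m <- ofat_measures(val, base, "N_LIMP", delta = 0.10, integer = TRUE)
  expect_equal(m$sm_plus, 1, tolerance = 1e-9)   # exact for a linear map
})

test_that("proliferation features mirror the balanced composition", {
  p <- baseline_params("SCC")
  ft <- proliferation_features(p)
  b <- balanced_composition(p)
  expect_equal(ft$T_d, 109, tolerance = 1e-4)
  expect_equal(ft$SLF, ft$SF / ft$LF)
  expect_equal(ft$SDF, ft$SF / b$DF, tolerance = 1e-12)
  expect_equal(ft$GF, 0.36, tolerance = 1e-6)
})
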