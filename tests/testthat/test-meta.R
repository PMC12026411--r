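test_that("DerSimonian-Laird pooling matches hand-derived values", {
    # single study passes through
    m1 <- dlMeta(0.4, 0.1)
    expect_equal(m1$beta_pooled, 0.4)
    expect_equal(m1$se_pooled, 0.1)
    expect_equal(m1$tau2, 0)
    expect_equal(m1$Q, 0)
    # two identical studies: no heterogeneity, se shrinks by sqrt(2)
    m2 <- dlMeta(c(0.3, 0.3), c(0.1, 0.1))
    expect_equal(m2$beta_pooled, 0.3)
    expect_equal(m2$tau2, 0)
    expect_equal(m2$se_pooled, 0.1 / sqrt(2))
    # worked example: w = (100, 100), beta_FE = 0.3, Q = 8,
    # tau2 = (8-1)/(200-100) = 0.07, w* = 12.5 each -> beta 0.3, se 0.2
    m3 <- dlMeta(c(0.5, 0.1), c(0.1, 0.1))
    expect_equal(m3$Q, 8)
    expect_equal(m3$tau2, 0.07)
    expect_equal(m3$beta_pooled, 0.3)
    expect_equal(m3$se_pooled, 0.2)
    expect_equal(m3$p, 2 * pnorm(-1.5), tolerance = 1e-12)
    expect_error(dlMeta(numeric(), numeric()), "at least one")
})

test_that("DL estimator agrees with an independent implementation", {
    set.seed(10)
    for (i in 1:50) {
        k <- sample(2:6, 1)
        beta <- rnorm(k, 0, 0.5)
        se <- runif(k, 0.05, 0.4)
        ours <- dlMeta(beta, se)
        ref <- metafor::rma(yi = beta, sei = se, method = "DL")
        expect_equal(ours$beta_pooled, as.numeric(ref$b), tolerance = 1e-8)
        expect_equal(ours$se_pooled, ref$se, tolerance = 1e-8)
        expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
        expect_equal(ours$Q, ref$QE, tolerance = 1e-8)
        # tau2 >= 0 and se_pooled <= min(se) when tau2 = 0
        if (ours$tau2 == 0) expect_lte(ours$se_pooled, min(se) + 1e-12)
    }
    # no heterogeneity when all effects are equal
    expect_equal(dlMeta(rep(0.2, 4), c(0.1, 0.2, 0.1, 0.3))$tau2, 0)
})

test_that("vectorized two-study meta equals the scalar path", {
    set.seed(11)
    b1 <- rnorm(20); b2 <- rnorm(20)
    s1 <- runif(20, 0.05, 0.3); s2 <- runif(20, 0.05, 0.3)
    vec <- sceTR:::dlMeta2Vec(b1, s1, b2, s2)
    for (i in seq_len(20)) {
        sc <- dlMeta(c(b1[i], b2[i]), c(s1[i], s2[i]))
        expect_equal(vec$beta_pooled[i], sc$beta_pooled, tolerance = 1e-12)
        expect_equal(vec$p[i], sc$p, tolerance = 1e-12)
        expect_equal(vec$tau2[i], sc$tau2, tolerance = 1e-12)
    }
})

test_that("specificity classifier follows the p_meta vs p_origin rule", {
    origin <- data.frame(beta = 0.5, se = 0.07, p = 1e-10)
    # identical effect elsewhere: pooling gains power, p_meta < p_origin,
    # so the sc-eTR is shared (verified numerically via dlMeta)
    same <- data.frame(cell_type = "CTB", beta = 0.5, se = 0.07,
                       expressed_fraction = 0.5)
    cl <- classifySpecificity(origin, same)
    expect_true(cl$comparisons$shared[1])
    expect_lt(cl$comparisons$p_meta[1], origin$p)
    expect_false(cl$specific)
    # null effects elsewhere: meta p-value degrades in every comparison
    nulls <- data.frame(cell_type = paste0("CT", 1:5),
                        beta = c(0, 0.01, -0.02, 0, 0.01),
                        se = rep(0.07, 5),
                        expressed_fraction = rep(0.5, 5))
    cl2 <- classifySpecificity(origin, nulls)
    expect_equal(cl2$n_shared, 0L)
    expect_true(cl2$specific)
    # one strong concordant comparison breaks specificity
    mix <- rbind(nulls, same)
    cl3 <- classifySpecificity(origin, mix)
    expect_false(cl3$specific)
    expect_equal(cl3$n_shared, 1L)
    # below the 1% expressed filter the comparison is ineligible
    offf <- data.frame(cell_type = "CTX", beta = 0.5, se = 0.07,
                       expressed_fraction = 0.005)
    cl4 <- classifySpecificity(origin, offf)
    expect_false(cl4$defined)
    expect_false(cl4$specific)
})

test_that("permutation of genotype labels yields calibrated null p-values", {
    set.seed(12)
    n <- 150; L <- 30
    dos <- lapply(1:2, function(i)
        matrix(rbinom(n * L, 4, 0.4) + 10, n,
               dimnames = list(paste0("c", i, "_s", 1:n),
                               paste0("TR", 1:L))))
    cov_ <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 10))
    pbs <- lapply(1:2, function(i) {
        # expression depends on the genotypes so only permutation
        # breaks the link
        y <- t(sapply(1:L, function(j) 0.3 * dos[[i]][, j] + rnorm(n)))
        rownames(y) <- paste0("G", 1:L)
        colnames(y) <- rownames(dos[[i]])
        PseudobulkMatrix(y, setNames(rep(0.5, L), rownames(y)), cov_,
                         "CT1", paste0("cohort", i))
    })
    windows <- setNames(as.list(paste0("TR", 1:L)), paste0("G", 1:L))
    calib <- permutationCalibration(dos, pbs, windows, seed = 99)
    expect_equal(calib$n_tests, L)
    r05 <- calib$rates[calib$rates$alpha == 0.05, ]
    expect_lt(abs(r05$rate - 0.05), 3 * sqrt(0.05 * 0.95 / L) + 1e-9)
    expect_gt(calib$ks_p, 0.01)
    # alpha = 1 always rejects; fixed seed reproduces exactly
    expect_equal(mean(calib$p < 1), 1)
    calib2 <- permutationCalibration(dos, pbs, windows, seed = 99)
    expect_identical(calib$p, calib2$p)
})

test_that("sign-discordant significant pairs are reported", {
    st <- data.frame(cell_type = c("A", "B", "C"),
                     beta = c(0.9, -0.4, 0.2),
                     p = c(1e-81, 1e-13, 0.4))
    out <- signDiscordantPairs(st)
    expect_equal(nrow(out), 1L)
    expect_setequal(c(out$cell_type_a, out$cell_type_b), c("A", "B"))
})
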