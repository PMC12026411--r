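test_that("log ABF matches numerical integration of the marginal likelihoods", {
    # ABF = int N(bhat; b, V) N(b; 0, W) db / N(bhat; 0, V)
    beta <- 0.5; se <- 0.1; W <- 0.0225
    num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, sqrt(W)),
                     -2, 2)$value
    expect_equal(logABF(beta, se, W), log(num / dnorm(beta, 0, se)),
                 tolerance = 1e-8)
    expect_equal(exp(logABF(beta, se, W)), 3.2e3, tolerance = 0.01)
    # z = 0 favors the null
    expect_lt(logABF(0, 0.1, 0.05), 0)
    expect_equal(logABF(0, 0.1, 0.05), 0.5 * log(0.01 / 0.06))
    # W -> 0 brings the Bayes factor to 1
    expect_equal(logABF(0.5, 0.1, 1e-12), 0, tolerance = 1e-6)
    # monotone in |z| at fixed V, W
    z <- seq(0, 6, by = 0.5)
    lb <- logABF(z * 0.1, 0.1, 0.04)
    expect_true(all(diff(lb) > 0))
})

test_that("single-effect fine-mapping equals brute-force enumeration", {
    expect_equal(singleEffectFinemap(
        data.frame(variant = "v1", beta = 0.3, se = 0.1))$pip$pip, 1)
    # identical statistics share the posterior uniformly
    k <- 5
    fm <- singleEffectFinemap(data.frame(variant = paste0("v", 1:k),
                                         beta = 0.3, se = 0.1))
    expect_equal(fm$pip$pip, rep(1 / k, k))
    set.seed(30)
    for (i in 1:50) {
        J <- sample(2:20, 1)
        st <- data.frame(variant = paste0("v", 1:J),
                         beta = rnorm(J, 0, 0.3),
                         se = runif(J, 0.05, 0.2))
        fm <- singleEffectFinemap(st)
        oracle <- bruteForcePIP(st$beta, st$se, fm$W_star)
        expect_equal(fm$pip$pip, oracle, tolerance = 1e-10)
        expect_equal(sum(fm$pip$pip), 1, tolerance = 1e-12)
        # permutation invariance of the PIPs
        perm <- sample(J)
        fm2 <- singleEffectFinemap(st[perm, ])
        expect_equal(fm2$pip$pip, fm$pip$pip[perm], tolerance = 1e-12)
        # credible set is the smallest PIP-ranked set reaching 95%
        o <- order(fm$pip$pip, decreasing = TRUE)
        size <- which(cumsum(fm$pip$pip[o]) >= 0.95)[1]
        expect_equal(sum(fm$pip$in_credible_set), size)
        expect_identical(fm$pip$pruned, !fm$pip$in_credible_set)
    }
    expect_error(singleEffectFinemap(
        data.frame(variant = "v", beta = NA, se = NA)), "degenerate")
})

test_that("candidate-causal calls require lead status and PIP >= 0.7", {
    fm <- list(pip = data.frame(variant = c("tr1", "snv1"),
                                pip = c(0.75, 0.25)))
    expect_true(callCandidateCausal(fm, "tr1", "tr1")$passes)
    fm$pip$pip <- c(0.5, 0.5)
    expect_false(callCandidateCausal(fm, "tr1", "tr1")$passes)
    fm$pip$pip <- c(0.9, 0.1)
    # strongest signal held by the SNV: TR not candidate causal
    expect_false(callCandidateCausal(fm, "tr1", "snv1")$passes)
    # boundary: PIP exactly 0.7 passes
    fm$pip$pip <- c(0.7, 0.3)
    expect_true(callCandidateCausal(fm, "tr1", "tr1")$passes)
})

test_that("conditional analysis distinguishes causal variants from tags", {
    set.seed(31)
    n <- 800
    g_causal <- rbinom(n, 4, 0.5) + 20
    # strong but imperfect tag of the causal variant
    g_tag <- as.numeric(g_causal > 22) + rbinom(n, 1, 0.3)
    g_indep <- rnorm(n)
    y <- 0.5 * scale(g_causal)[, 1] + rnorm(n)
    # conditioning on an uncorrelated variant leaves beta unchanged
    plain <- fitAssociation(y, g_causal)
    cond0 <- conditionalAssociation(y, g_causal, g_indep)
    expect_equal(cond0$beta, plain$beta, tolerance = 1e-2)
    # the causal variant survives conditioning on its tag ...
    condc <- conditionalAssociation(y, g_causal, g_tag)
    expect_lt(condc$p, 1e-8)
    # ... but the tag is abolished by conditioning on the causal variant
    condt <- conditionalAssociation(y, g_tag, g_causal)
    expect_gt(condt$p, 1e-4)
    # a perfect duplicate is rejected as collinear
    expect_error(conditionalAssociation(y, g_causal, g_causal),
                 "collinear")
})

test_that("dosage LD is the squared Pearson correlation", {
    expect_equal(ldR2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)), 1)
    # perfect negative correlation squares to 1
    expect_equal(ldR2(c(0, 1, 2, 0, 1, 2), c(2, 1, 0, 2, 1, 0)), 1)
    expect_error(ldR2(rep(1, 10), rnorm(10)), "constant")
    expect_error(ldR2(c(1, NA, NA, 2), c(1, NA, NA, 2)), "at least 3")
    set.seed(32)
    a <- rnorm(100); b <- rnorm(100)
    expect_equal(ldR2(a, b), cor(a, b)^2, tolerance = 1e-12)
})

test_that("TR-representing indels are pruned before fine-mapping", {
    catalog <- TRCatalog(c("chr1", "chr1"), c(101, 1001), c(160, 1030),
                         motif = c("AT", "CAG"))
    indels <- data.frame(
        chrom = c("chr1", "chr1", "chr1", "chr1"),
        pos = c(120, 120, 5000, 1010),
        ref = c("GATAT", "G", "GATAT", "G"),
        alt = c("G", "GATA", "G", "GAGC"))  # AGC = rotation of CAG
    pr <- pruneTRIndels(indels, catalog)
    # whole-copy deletion inside the locus removed; partial copy kept;
    # same indel outside any locus kept; rotated whole copy removed
    expect_equal(pr$removed$pos, c(120, 1010))
    expect_equal(pr$retained$pos, c(120, 5000))
})
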