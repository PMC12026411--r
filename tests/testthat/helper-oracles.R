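# independent oracles shared by module and acceptance tests

# direct oracle: the Cauchy-combination statistic evaluated through the
# standard Cauchy distribution functions, independent of acatCombine's
# stabilized code path
acatOracle <- function(p, w = rep(1, length(p))) {
    w <- w / sum(w)
    T_ <- sum(w * qcauchy(p, lower.tail = FALSE))
    pcauchy(T_, lower.tail = FALSE)
}


# brute-force one-causal-variant posterior: explicit marginal likelihood
# of each "variant j is causal" hypothesis from the normal approximation,
# independent of the ABF-softmax implementation path
bruteForcePIP <- function(beta, se, W) {
    logL <- vapply(seq_along(beta), function(j)
        sum(dnorm(beta, 0, ifelse(seq_along(beta) == j,
                                  sqrt(se^2 + W), se), log = TRUE)),
        numeric(1))
    exp(logL - max(logL)) / sum(exp(logL - max(logL)))
}


# brute-force enumeration over all causal-configuration pairs:
# study 1 causal at i (or none), study 2 causal at j (or none), with
# per-configuration priors p1, p2, p12 and Wakefield ABFs
bruteForceColoc <- function(b1, s1, b2, s2, p1 = 1e-4, p2 = 1e-4,
                            p12 = 1e-5, W1 = 0.0225, W2 = 0.0225) {
    abf1 <- exp(logABF(b1, s1, W1))
    abf2 <- exp(logABF(b2, s2, W2))
    J <- length(b1)
    L <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
    for (i in seq_len(J)) L["H1"] <- L["H1"] + p1 * abf1[i]
    for (j in seq_len(J)) L["H2"] <- L["H2"] + p2 * abf2[j]
    for (i in seq_len(J)) for (j in seq_len(J)) {
        if (i == j) L["H4"] <- L["H4"] + p12 * abf1[i] * abf2[j]
        else L["H3"] <- L["H3"] + p1 * p2 * abf1[i] * abf2[j]
    }
    L / sum(L)
}

mkStats <- function(beta, se, ids = paste0("v", seq_along(beta))) {
    data.frame(variant = ids, beta = beta, se = se)
}

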