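test_that("fully separated groups of 3 give the exact two-sided p of 0.1", {
    m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
    st <- matrixStudy(m, 3, 3)
    tab <- deTable(wilcoxonDE(st, alpha = 0.2))
    expect_equal(tab$p_value, 2 / 20)     # 2 of C(6,3)=20 orderings
    expect_equal(tab$statistic, 9)        # U of the case group
    expect_identical(tab$direction, "up_in_case")
    expect_true(tab$significant)
    expect_false(deTable(wilcoxonDE(st, alpha = 0.05))$significant)
})

test_that("constant genes get p = 1 and are never significant", {
    m <- rbind(flat = rep(5, 8), same = rep(c(1, 2), 4))
    st <- matrixStudy(m, 4, 4)
    tab <- deTable(wilcoxonDE(st, alpha = 0.99))
    expect_equal(tab$p_value[tab$gene == "flat"], 1)
    expect_false(any(tab$significant[tab$gene == "flat"]))
})

test_that("exact p-values match brute-force enumeration, ties included", {
    set.seed(41)
    for (sizes in list(c(2, 3), c(4, 4), c(5, 6), c(6, 8))) {
        n1 <- sizes[1]; n2 <- sizes[2]
        vals <- rbind(rnorm(n1 + n2),
                      sample(rep(1:3, length.out = n1 + n2)),  # heavy ties
                      c(rep(0, n1), rnorm(n2)))                # partial ties
        rownames(vals) <- paste0("g", 1:3)
        st <- matrixStudy(vals, n1, n2)
        got <- deTable(wilcoxonDE(st, alpha = 0.05))$p_value
        want <- apply(vals, 1, bruteWilcoxonP, nCT = n1)
        expect_equal(got, unname(want), tolerance = 1e-14)
    }
})

test_that("tie-free p-values agree with the exact wilcox.test reference", {
    set.seed(43)
    m <- matrix(rnorm(30 * 13), 30, 13)
    st <- matrixStudy(m, 6, 7)
    got <- deTable(wilcoxonDE(st, alpha = 0.05))$p_value
    want <- apply(m, 1, function(v)
        wilcox.test(v[1:6], v[7:13], exact = TRUE)$p.value)
    expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("groups below the design minimum are a configuration error", {
    m <- matrix(rnorm(8), 2, 4)
    st <- matrixStudy(m, 2, 2)
    expect_error(wilcoxonDE(st[, c(1, 3, 4)]), ">= 2 samples")
})

test_that("SAM d reduces to the pooled t-like statistic when s0 = 0", {
    set.seed(47)
    x <- matrix(rnorm(14), 1, 14)
    ct <- 1:7; pd <- 8:14
    d <- gcnet:::samStatistics(x, ct, pd, s0 = 0)$d
    num <- mean(x[pd]) - mean(x[ct])
    pooled <- sqrt(((sum((x[ct] - mean(x[ct]))^2) +
                     sum((x[pd] - mean(x[pd]))^2)) / 12) * (1 / 7 + 1 / 7))
    expect_equal(unname(d), num / pooled, tolerance = 1e-12)
})

test_that("SAM with a fixed seed is fully reproducible", {
    sim <- generateStudy(syntheticConfig(n_probes = 300,
                                         n_genes_annotated = 300,
                                         n_ct = 7, n_pd = 7, n_modules = 0,
                                         de_fraction = 0.1, de_effect = 2,
                                         noise_sd = 0.5, flag_rate = 0,
                                         bias_amplitude = 0, seed = 53))
    a <- samDE(sim$study, targetFDR = 0.05, nPermutations = 150, seed = 9)
    b <- samDE(sim$study, targetFDR = 0.05, nPermutations = 150, seed = 9)
    expect_identical(deTable(a), deTable(b))
    expect_identical(a@params$delta, b@params$delta)
})

test_that("SAM call set shrinks as delta grows and recovers planted DE", {
    sim <- generateStudy(syntheticConfig(n_probes = 500,
                                         n_genes_annotated = 500,
                                         n_ct = 7, n_pd = 7, n_modules = 0,
                                         de_fraction = 0.05, de_effect = 2,
                                         noise_sd = 0.5, flag_rate = 0,
                                         bias_amplitude = 0, seed = 59))
    st <- collapseProbes(sim$study)  # index by gene symbol like the truth
    de <- samDE(st, targetFDR = 0.05, nPermutations = 150, seed = 1)
    called <- significantGenes(de)
    truthde <- truthDEGenes(sim$truth)
    expect_gte(mean(truthde %in% called), 0.8)
    expect_lte(mean(!called %in% truthde), 0.10)

    # monotone nesting of the delta band
    x <- intensities(st)
    g <- sampleGroups(st)
    obs <- gcnet:::samStatistics(x, which(g == "CT"), which(g == "PD"),
                                 s0 = de@params$s0)
    dsort <- sort(obs$d)
    perms <- gcnet:::samPermutations(14, 7, 150, 1)
    dstar <- apply(perms, 2, function(ctb)
        sort(gcnet:::samStatistics(x, ctb, setdiff(1:14, ctb),
                                   de@params$s0)$d))
    dbar <- rowMeans(dstar)
    sizes <- vapply(c(0.2, 0.5, 1, 2), function(delta) {
        cuts <- gcnet:::samCuts(dsort, dbar, delta)
        sum(obs$d >= cuts$cutup | obs$d <= cuts$cutlow)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
})

test_that("null data yield at most trivial SAM call sets", {
    sizes <- vapply(1:8, function(s) {
        sim <- generateStudy(syntheticConfig(n_probes = 300,
                                             n_genes_annotated = 300,
                                             n_ct = 6, n_pd = 8,
                                             n_modules = 0, de_fraction = 0,
                                             noise_sd = 0.5, flag_rate = 0,
                                             bias_amplitude = 0,
                                             seed = 100 + s))
        suppressWarnings(
            length(significantGenes(samDE(sim$study, 0.05, 100, seed = s))))
    }, numeric(1))
    # the auto-delta finder may admit a handful of stray genes on pure
    # noise, but never more than ~1% of the tested genes
    expect_lte(median(sizes), 2)
    expect_lte(max(sizes), 0.01 * 300)
})

test_that("significant genes are restricted to GO-annotated symbols", {
    set.seed(61)
    m <- matrix(rnorm(40, 8), 10, 4)
    m[1:4, 3:4] <- m[1:4, 3:4] + 50    # force separation
    ann <- data.frame(probe_id = sprintf("g%03d", 1:10),
                      gene_symbol = LETTERS[1:10],
                      go_annotated = rep(c(TRUE, FALSE), 5))
    st <- matrixStudy(m, 2, 2, annotation = ann)
    st <- collapseProbes(st)
    de <- wilcoxonDE(st, alpha = 0.5)
    sel <- selectDEGenes(de, st)
    expect_true(all(sel %in% LETTERS[seq(1, 9, 2)]))
    expect_identical(sel, sort(unique(sel)))

    none <- wilcoxonDE(st, alpha = 1e-9)
    expect_error(selectDEGenes(none, st), "no significant")
})
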