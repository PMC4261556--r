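test_that("perfect and anti-correlated pairs follow the thresholding mode", {
    m <- rbind(a = c(1, 2, 3, 4),
               b = c(2, 4, 6, 8),       # r = +1 with a
               c = c(4, 3, 2, 1))       # r = -1 with a and b
    st <- matrixStudy(m, 2, 2)
    net_abs <- buildNetwork(st, c("a", "b", "c"), 0.9, "absolute")
    expect_identical(nrow(networkEdges(net_abs)), 3L)
    net_pos <- buildNetwork(st, c("a", "b", "c"), 0.9, "positive")
    e <- networkEdges(net_pos)
    expect_identical(nrow(e), 1L)
    expect_identical(c(e$gene_a, e$gene_b), c("a", "b"))
    expect_equal(e$r, 1)
})

test_that("edges match the brute-force all-pairs oracle on 50 genes", {
    sim <- generateStudy(syntheticConfig(n_probes = 50,
                                         n_genes_annotated = 50,
                                         n_modules = 2,
                                         module_sizes = c(15, 15),
                                         member_loading = 0.8,
                                         noise_sd = 0.5, flag_rate = 0,
                                         bias_amplitude = 0,
                                         de_fraction = 0, seed = 67))
    st <- collapseProbes(sim$study)
    genes <- rownames(st)
    for (thr in c(0.5, 0.8)) {
        net <- buildNetwork(st, genes, thr)
        got <- sprintf("%s|%s", networkEdges(net)$gene_a,
                       networkEdges(net)$gene_b)
        x <- intensities(st)
        want <- character(0)
        for (i in seq_along(genes)) for (j in seq_along(genes)) {
            if (i < j && abs(cor(x[genes[i], ], x[genes[j], ])) >= thr) {
                pair <- sort(c(genes[i], genes[j]))
                want <- c(want, sprintf("%s|%s", pair[1], pair[2]))
            }
        }
        expect_setequal(got, want)
    }
})

test_that("threshold nesting, handshake identity and order invariance hold", {
    sim <- generateStudy(syntheticConfig(n_probes = 60,
                                         n_genes_annotated = 60,
                                         n_modules = 2,
                                         module_sizes = c(20, 20),
                                         flag_rate = 0, bias_amplitude = 0,
                                         de_fraction = 0, seed = 71))
    st <- collapseProbes(sim$study)
    genes <- rownames(st)
    key <- function(net) sprintf("%s|%s", networkEdges(net)$gene_a,
                                 networkEdges(net)$gene_b)
    lo <- buildNetwork(st, genes, 0.5)
    hi <- buildNetwork(st, genes, 0.8)
    expect_true(all(key(hi) %in% key(lo)))
    for (net in list(lo, hi))
        expect_identical(sum(nodeDegrees(net)),
                         2L * nrow(networkEdges(net)))
    shuffled <- buildNetwork(st, rev(genes), 0.5)
    expect_identical(networkGenes(shuffled), networkGenes(lo))
    expect_identical(networkEdges(shuffled), networkEdges(lo))
})

test_that("zero-variance genes are excluded with a warning", {
    m <- rbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 3, 4.2),
               flat = rep(7, 4))
    st <- matrixStudy(m, 2, 2)
    expect_warning(net <- buildNetwork(st, c("a", "b", "flat"), 0.9),
                   "zero-variance")
    expect_false("flat" %in% c(networkEdges(net)$gene_a,
                               networkEdges(net)$gene_b))
    expect_error(buildNetwork(st, c("a", "b"), 1.5), "threshold")
})

test_that("mean connectivity is 2L/N with two-decimal display truncation", {
    expect_equal(meanConnectivity(4, L = 0), 0)
    expect_equal(meanConnectivity(206, L = 670), 2 * 670 / 206)
    expect_identical(formatConnectivity(meanConnectivity(206, L = 670)),
                     "6.50")
    expect_identical(formatConnectivity(meanConnectivity(209, L = 586)),
                     "5.60")   # 5.6076... truncates, does not round to 5.61
})

test_that("chooseThreshold returns the minimal network reaching the target", {
    sim <- generateStudy(syntheticConfig(n_probes = 40,
                                         n_genes_annotated = 40,
                                         n_modules = 1, module_sizes = 20L,
                                         flag_rate = 0, bias_amplitude = 0,
                                         de_fraction = 0, seed = 73))
    st <- collapseProbes(sim$study)
    genes <- rownames(st)
    cm <- abs(cor(t(intensities(st)[genes, ])))
    vals <- sort(cm[upper.tri(cm)], decreasing = TRUE)

    expect_equal(chooseThreshold(st, genes, 1), vals[1])
    expect_equal(chooseThreshold(st, genes, length(vals)),
                 vals[length(vals)])
    for (target in c(10, 100)) {
        thr <- chooseThreshold(st, genes, target)
        expect_equal(thr, vals[target])
        L <- nrow(networkEdges(buildNetwork(st, genes, thr)))
        expect_gte(L, target)
    }
    expect_error(chooseThreshold(st, genes, length(vals) + 1), "exceeds")
})

test_that("degree table ranks hubs with boundary-tie inclusion", {
    star <- toyNetwork(starEdges("HUB", 4))
    ht <- degreeTable(star, "top_n", n = 1)
    expect_identical(hubGenes(ht), "HUB")
    expect_identical(hubTable(ht)$degree[1], 4L)

    # leaves all tie at degree 1: top_n = 2 pulls in every leaf
    ht2 <- degreeTable(star, "top_n", n = 2)
    expect_identical(sort(hubGenes(ht2)),
                     sort(c("HUB", sprintf("L%02d", 1:4))))

    empty <- toyNetwork(data.frame(gene_a = character(0),
                                   gene_b = character(0), r = numeric(0)),
                        genes = c("A", "B", "C"))
    expect_length(hubGenes(degreeTable(empty, "quantile", q = 0.9)), 0)
    expect_length(hubGenes(degreeTable(empty, "top_n", n = 2)), 0)
})

test_that("planted hubs dominate the degree ranking of their network", {
    hits <- vapply(1:5, function(s) {
        sim <- generateStudy(syntheticConfig(seed = 200 + s,
                                             flag_rate = 0,
                                             bias_amplitude = 0,
                                             de_fraction = 0))
        st <- collapseProbes(sim$study)
        tr <- sim$truth
        genes <- names(truthModules(tr))[!is.na(truthModules(tr))]
        thr <- chooseThreshold(st, genes, 650)
        ht <- degreeTable(buildNetwork(st, genes, thr), "top_n", n = 10)
        mean(hubGenes(tr) %in% hubGenes(ht))
    }, numeric(1))
    expect_gte(mean(hits), 0.75)
})
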