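test_that("identical networks make every hub common with equal degrees", {
    e <- rbind(starEdges("HUB", 6), data.frame(gene_a = "L01",
                                               gene_b = "L02", r = 0.92))
    net <- toyNetwork(e, label = "X-CT")
    ht <- degreeTable(net, "top_n", n = 3)
    rep <- compareNetworks(net, net, ht, ht)
    rows <- comparisonRows(rep)
    expect_true(all(rows$hub_in == "both"))
    expect_identical(rows$degree_ct, rows$degree_pd)
    expect_setequal(commonHubs(rep), hubGenes(ht))
})

test_that("a common hub row carries its degree in both networks", {
    # a gene hub in both networks with 16 links in CT and 26 in PD
    net_ct <- toyNetwork(starEdges("H", 16), threshold = 0.94,
                         label = "VA-CT")
    net_pd <- toyNetwork(starEdges("H", 26), threshold = 0.94,
                         label = "VA-PD")
    rep <- compareNetworks(net_ct, net_pd,
                           degreeTable(net_ct, "top_n", n = 1),
                           degreeTable(net_pd, "top_n", n = 1))
    row <- comparisonRows(rep)[1, ]
    expect_identical(row$gene, "H")
    expect_identical(row$degree_ct, 16L)
    expect_identical(row$degree_pd, 26L)
    expect_identical(row$hub_in, "both")
    expect_identical(commonHubs(rep), "H")
})

test_that("comparison is symmetric up to column swap and flags absence", {
    net_ct <- toyNetwork(starEdges("A", 5), genes = c("A", sprintf("L%02d", 1:5), "ONLYCT"))
    net_pd <- toyNetwork(starEdges("B", 4))
    hct <- degreeTable(net_ct, "top_n", n = 1)
    hpd <- degreeTable(net_pd, "top_n", n = 1)
    foreign <- toyNetwork(starEdges("Q", 3, prefix = "Z"))
    expect_error(compareNetworks(net_ct, foreign, hct,
                                 degreeTable(foreign, "top_n", n = 1)),
                 "share no genes")

    net_pd2 <- toyNetwork(rbind(starEdges("B", 4), starEdges("A", 2, prefix = "L")))
    hpd2 <- degreeTable(net_pd2, "top_n", n = 1)
    fwd <- compareNetworks(net_ct, net_pd2, hct, hpd2)
    swp <- compareNetworks(net_pd2, net_ct, hpd2, hct)
    f <- comparisonRows(fwd); s <- comparisonRows(swp)
    s <- s[match(f$gene, s$gene), ]
    expect_identical(f$degree_ct, s$degree_pd)
    expect_identical(f$degree_pd, s$degree_ct)
    expect_identical(f$hub_in == "both", s$hub_in == "both")
    # gene B is not a node of the CT network: degree 0 plus absence marker
    expect_identical(f$degree_ct[f$gene == "B"], 0L)
    expect_false(f$present_ct[f$gene == "B"])
    expect_true(f$present_pd[f$gene == "B"])
    # common hubs are the intersection of the hub sets
    expect_identical(commonHubs(fwd),
                     sort(intersect(hubGenes(hct), hubGenes(hpd2))))
})

test_that("hub-module dispersion contrasts a 2-module CT vs merged PD", {
    set.seed(79)
    n_ct <- 6; n_pd <- 8
    f_ct <- matrix(rnorm(2 * n_ct), 2)       # two factors in CT
    f_pd <- matrix(rnorm(1 * n_pd), 1)       # merged single factor in PD
    genes <- sprintf("M%02d", 1:12)
    mk <- function(f, members) {
        x <- t(vapply(members, function(m) f[m, ] + rnorm(ncol(f), sd = 0.1),
                      numeric(ncol(f))))
        rownames(x) <- genes
        x
    }
    x_ct <- mk(f_ct, rep(1:2, each = 6))
    x_pd <- mk(f_pd, rep(1, 12))
    m_all <- cbind(x_ct, x_pd)
    colnames(m_all) <- c(paste0("c", 1:n_ct), paste0("p", 1:n_pd))
    groups <- setNames(rep(c("CT", "PD"), c(n_ct, n_pd)), colnames(m_all))
    st <- ExpressionStudy(m_all, groups = groups)
    halves <- splitByGroup(st)

    nets <- lapply(halves, buildNetwork, geneList = genes, threshold = 0.8)
    hubs <- lapply(nets, degreeTable, rule = "top_n", n = 2)
    parts <- lapply(nets, detectModules)
    rep <- compareNetworks(nets$CT, nets$PD, hubs$CT, hubs$PD, parts)
    s <- comparisonSummary(rep)
    expect_identical(s$hub_modules[s$condition == "CT"], 2L)
    expect_identical(s$hub_modules[s$condition == "PD"], 1L)
})

test_that("runContrast is deterministic and reproduces planted contrast", {
    cfg <- contrastConfig(de_method = "wilcoxon", alpha = 0.005,
                          target_edges = 100L, label = "SYN", seed = 5)
    sim <- generateStudy(syntheticConfig(n_probes = 800,
                                         n_genes_annotated = 600,
                                         n_modules = 0, de_fraction = 0.1,
                                         de_effect = 2.5, noise_sd = 0.5,
                                         seed = 83))
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    r1 <- runContrast(sim$study, cfg, outDir = d1)
    r2 <- runContrast(sim$study, cfg, outDir = d2)
    for (f in c("report_hubs.tsv", "report_summary.tsv", "report.json",
                "de_results.tsv", "network_CT.sif", "network_PD.sif",
                "edges_CT.tsv", "edges_PD.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)),
                         info = f)
    # selected genes are planted DE genes (GO-annotated only)
    expect_true(all(r1$genes %in% names(truthModules(sim$truth))))
    expect_gte(mean(r1$genes %in% truthDEGenes(sim$truth)), 0.8)
    expect_identical(conditionLabel(r1$networks$CT), "SYN-CT")

    # a null config dies at the documented selection stage (alpha below
    # the smallest achievable exact p, so no chance calls survive)
    null_sim <- generateStudy(syntheticConfig(n_probes = 300,
                                              n_genes_annotated = 200,
                                              n_modules = 0,
                                              de_fraction = 0, seed = 89))
    cfg_null <- contrastConfig(de_method = "wilcoxon", alpha = 1e-4)
    expect_error(runContrast(null_sim$study, cfg_null), "\\[select\\]")
})
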