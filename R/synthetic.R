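#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of \code{\link{generateStudy}}.
#' Defaults emulate the structure of a postmortem brain one-color
#' microarray case-control study: a few thousand probes of which a subset
#' is GO-annotated, 6 control vs 8 case samples, four planted correlation
#' modules of 30 genes each with one high-loading hub per module, log2
#' intensities with intensity-dependent per-array bias, sparse QC flags
#' and a small fraction of genes upregulated in the case group.
#'
#' @param n_probes total probes on the array.
#' @param n_genes_annotated number of probes mapping to GO-annotated
#'   genes (<= \code{n_probes}); the remainder are unannotated background.
#' @param n_ct,n_pd samples in the control (CT) and case (PD) groups
#'   (each >= 2).
#' @param n_modules number of planted correlation modules.
#' @param module_sizes integer vector of length \code{n_modules}; their
#'   sum must not exceed \code{n_genes_annotated}.
#' @param hub_loading,member_loading gene-factor correlation of the
#'   designated hub / ordinary members, in (0, 1];
#'   \code{hub_loading >= member_loading}.
#' @param noise_sd residual noise scale in log2 units (the sd of a
#'   zero-loading gene around its baseline).
#' @param de_fraction fraction of annotated genes upregulated in the case
#'   group, in [0, 1].
#' @param de_effect log2 fold-change added to DE genes in case samples.
#' @param flag_rate probability that a spot carries at least one QC flag.
#' @param bias_amplitude amplitude (log2 units) of the smooth monotone
#'   intensity-dependent per-array bias.
#' @param seed integer RNG seed; identical configs generate identical
#'   studies.
#'
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @seealso \code{\link{generateStudy}}
#' @export
syntheticConfig <- function(n_probes = 2000L,
                            n_genes_annotated = 1000L,
                            n_ct = 6L, n_pd = 8L,
                            n_modules = 4L,
                            module_sizes = rep(30L, n_modules),
                            hub_loading = 0.95,
                            member_loading = 0.8,
                            noise_sd = 0.5,
                            de_fraction = 0.05,
                            de_effect = 2.0,
                            flag_rate = 0.05,
                            bias_amplitude = 0.5,
                            seed = 1L) {
    cfg <- list(n_probes = as.integer(n_probes),
                n_genes_annotated = as.integer(n_genes_annotated),
                n_ct = as.integer(n_ct), n_pd = as.integer(n_pd),
                n_modules = as.integer(n_modules),
                module_sizes = as.integer(module_sizes),
                hub_loading = hub_loading,
                member_loading = member_loading,
                noise_sd = noise_sd,
                de_fraction = de_fraction, de_effect = de_effect,
                flag_rate = flag_rate, bias_amplitude = bias_amplitude,
                seed = as.integer(seed))
    class(cfg) <- "SyntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

validateSyntheticConfig <- function(cfg) {
    chk <- function(ok, field, why)
        if (!ok) .stopf("invalid SyntheticConfig field '%s': %s", field, why)
    chk(cfg$n_probes >= 1, "n_probes", "must be >= 1")
    chk(cfg$n_genes_annotated >= 0 &&
        cfg$n_genes_annotated <= cfg$n_probes,
        "n_genes_annotated", "must be in [0, n_probes]")
    chk(cfg$n_ct >= 2, "n_ct", "at least 2 samples per group")
    chk(cfg$n_pd >= 2, "n_pd", "at least 2 samples per group")
    chk(cfg$n_modules >= 0, "n_modules", "must be >= 0")
    chk(length(cfg$module_sizes) == cfg$n_modules, "module_sizes",
        "length must equal n_modules")
    chk(all(cfg$module_sizes >= 2) || cfg$n_modules == 0, "module_sizes",
        "each module needs >= 2 genes")
    chk(sum(cfg$module_sizes) <= cfg$n_genes_annotated, "module_sizes",
        "sum must not exceed n_genes_annotated")
    for (f in c("hub_loading", "member_loading"))
        chk(cfg[[f]] > 0 && cfg[[f]] <= 1, f, "must be in (0, 1]")
    chk(cfg$hub_loading >= cfg$member_loading, "hub_loading",
        "must be >= member_loading")
    chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
    for (f in c("de_fraction", "flag_rate"))
        chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
    chk(cfg$bias_amplitude >= 0, "bias_amplitude", "must be >= 0")
    invisible(cfg)
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path a YAML (or JSON) file whose keys are
#'   \code{\link{syntheticConfig}} arguments.
#' @return A validated \code{"SyntheticConfig"}.
#' @export
readSyntheticConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(syntheticConfig, vals)
}

#' Generate a synthetic case-control study with planted structure
#'
#' Simulates a one-color microarray study under a single-factor block
#' model. Each planted module m has a per-sample latent factor
#' \eqn{f_m \sim N(0,1)}; a member gene with loading \eqn{l} has log2
#' intensity
#' \deqn{x = baseline + l f_m + \sigma \sqrt{1 - l^2}\, \epsilon,}
#' with \eqn{\epsilon \sim N(0,1)} and \eqn{\sigma} = \code{noise_sd},
#' so \eqn{l} is the gene-factor correlation in the \eqn{\sigma = 1}
#' reference scale and the population correlation of two members is
#' \eqn{l_i l_j / \sqrt{(l_i^2 + \sigma^2(1-l_i^2))(l_j^2 + \sigma^2(1-l_j^2))}}.
#' The designated hub of each module (its first gene) receives
#' \code{hub_loading}, every other member \code{member_loading}; a gene
#' with loading 1 is an exact copy of its factor. Background genes have
#' loading 0. DE genes get \code{de_effect} added in case (PD) samples;
#' they are drawn from annotated genes outside the planted modules when
#' enough exist, so the differential signal does not distort module
#' correlations. Each array then receives a smooth monotone
#' intensity-dependent bias \eqn{a_s u^2} (u = baseline rank scaled to
#' (0,1]; \eqn{|a_s|} uniform in [0.5, 1] x \code{bias_amplitude},
#' random sign), exercising lowess removal. Per-spot flag counts are
#' Binomial(2, q) with \eqn{q = 1 - \sqrt{1 - flag\_rate}}, so a spot is
#' flagged with probability exactly \code{flag_rate} and occasionally
#' carries two flags.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return A list with elements \code{study}
#'   (\linkS4class{ExpressionStudy}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' sim <- generateStudy(syntheticConfig(n_probes = 200,
#'                                      n_genes_annotated = 100,
#'                                      n_modules = 2,
#'                                      module_sizes = c(10, 10),
#'                                      seed = 42))
#' sim$study
#' @export
generateStudy <- function(config) {
    validateSyntheticConfig(config)
    withSeed(config$seed, .generateStudyImpl(config))
}

.generateStudyImpl <- function(cfg) {
    nP <- cfg$n_probes
    nA <- cfg$n_genes_annotated
    nS <- cfg$n_ct + cfg$n_pd
    probes <- sprintf("P%05d", seq_len(nP))
    symbols <- c(sprintf("G%04d", seq_len(nA)),
                 sprintf("U%04d", seq_len(nP - nA)))
    samples <- c(sprintf("CT%d", seq_len(cfg$n_ct)),
                 sprintf("PD%d", seq_len(cfg$n_pd)))
    groups <- stats::setNames(rep(c("CT", "PD"), c(cfg$n_ct, cfg$n_pd)),
                              samples)
    is_pd <- groups[samples] == "PD"

    # module membership: annotated genes in leading blocks, hubs first
    moduleOf <- rep(NA_integer_, nA)
    loading <- numeric(nP)
    hub_idx <- integer(0)
    if (cfg$n_modules > 0) {
        stops <- cumsum(cfg$module_sizes)
        starts <- c(1L, utils::head(stops, -1) + 1L)
        for (m in seq_len(cfg$n_modules)) {
            idx <- starts[m]:stops[m]
            moduleOf[idx] <- m
            loading[idx] <- cfg$member_loading
            loading[starts[m]] <- cfg$hub_loading
        }
        hub_idx <- starts
    }

    # DE genes: prefer annotated genes outside modules
    n_de <- round(cfg$de_fraction * nA)
    de_idx <- integer(0)
    if (n_de > 0) {
        pool <- which(is.na(moduleOf))
        if (length(pool) < n_de) pool <- seq_len(nA)
        de_idx <- sort(sample(pool, n_de))
    }

    baseline <- stats::runif(nP, 6, 12)
    factors <- matrix(stats::rnorm(cfg$n_modules * nS), cfg$n_modules, nS)
    if (cfg$n_modules > 0 && nS > 1) {
        # standardize each factor across samples so every planted module
        # realizes its nominal strength in-sample; with 5-8 samples per
        # group the raw draws would make realized module strengths (and
        # hence recoverability) vary several-fold between modules
        factors <- (factors - rowMeans(factors)) /
            apply(factors, 1, stats::sd)
    }
    eps <- matrix(stats::rnorm(nP * nS), nP, nS)

    x <- baseline + cfg$noise_sd * sqrt(1 - loading^2) * eps
    if (cfg$n_modules > 0) {
        inmod <- which(!is.na(moduleOf))
        x[inmod, ] <- x[inmod, ] +
            loading[inmod] * factors[moduleOf[inmod], , drop = FALSE]
    }
    if (n_de > 0 && any(is_pd))
        x[de_idx, is_pd] <- x[de_idx, is_pd] + cfg$de_effect

    if (cfg$bias_amplitude > 0) {
        u <- rank(baseline, ties.method = "first") / nP
        amp <- cfg$bias_amplitude * sample(c(-1, 1), nS, replace = TRUE) *
            stats::runif(nS, 0.5, 1)
        x <- x + outer(u^2, amp)
    }
    dimnames(x) <- list(probes, samples)

    q <- 1 - sqrt(1 - cfg$flag_rate)
    flags <- matrix(stats::rbinom(nP * nS, 2L, q), nP, nS,
                    dimnames = list(probes, samples))

    annotation <- data.frame(
        probe_id = probes, gene_symbol = symbols,
        go_annotated = c(rep(TRUE, nA), rep(FALSE, nP - nA)),
        stringsAsFactors = FALSE)

    study <- ExpressionStudy(x, flags, groups, annotation)
    truth <- methods::new("SyntheticTruth",
        moduleOf = stats::setNames(moduleOf, symbols[seq_len(nA)]),
        hubGenes = symbols[hub_idx],
        deGenes = symbols[de_idx])
    list(study = study, truth = truth)
}

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("truthModules", "SyntheticTruth", function(x) x@moduleOf)

#' Accessors for SyntheticTruth
#'
#' \code{truthModules} returns the named gene-to-module map (NA =
#' background); \code{hubGenes} the planted hub genes; \code{truthDEGenes}
#' the planted case-upregulated genes.
#'
#' @param x a \linkS4class{SyntheticTruth}.
#' @name SyntheticTruth-accessors
NULL

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("hubGenes", "SyntheticTruth", function(x) x@hubGenes)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("truthDEGenes", "SyntheticTruth", function(x) x@deGenes)

setMethod("show", "SyntheticTruth", function(object) {
    nmod <- length(unique(object@moduleOf[!is.na(object@moduleOf)]))
    cat(sprintf(
        "SyntheticTruth: %d modules (%d genes), %d hubs, %d DE genes\n",
        nmod, sum(!is.na(object@moduleOf)), length(object@hubGenes),
        length(object@deGenes)))
    invisible(NULL)
})
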