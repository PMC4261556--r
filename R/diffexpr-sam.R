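# Two-class unpaired SAM statistics: d = (mean_PD - mean_CT) / (s + s0),
# s the pooled standard error of the difference.
samStatistics <- function(x, ct, pd, s0 = 0) {
    n1 <- length(ct); n2 <- length(pd)
    m1 <- rowMeans(x[, ct, drop = FALSE])
    m2 <- rowMeans(x[, pd, drop = FALSE])
    ss <- rowSums((x[, ct, drop = FALSE] - m1)^2) +
          rowSums((x[, pd, drop = FALSE] - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
    list(r = m2 - m1, s = s, d = (m2 - m1) / (s + s0))
}

# Fudge factor: the candidate percentile of s minimizing the coefficient
# of variation of window-wise MADs of d across intensity (s) windows.
chooseS0 <- function(r, s) {
    cand <- unique(c(0, stats::quantile(s, seq(0, 1, 0.05), names = FALSE)))
    br <- unique(stats::quantile(s, seq(0, 1, 0.01), names = FALSE))
    if (length(br) < 3) return(stats::median(s))
    grp <- cut(s, br, include.lowest = TRUE)
    cv <- vapply(cand, function(s0) {
        mads <- tapply(r / (s + s0), grp, stats::mad)
        mads <- mads[!is.na(mads) & mads > 0]
        if (length(mads) < 2) return(Inf)
        stats::sd(mads) / mean(mads)
    }, numeric(1))
    cand[which.min(cv)]
}

# label permutations: columns are size-n1 index sets taken as "CT"
samPermutations <- function(n, n1, nPermutations, seed) {
    if (choose(n, n1) <= nPermutations) {
        utils::combn(n, n1)
    } else {
        withSeed(seed,
            vapply(seq_len(nPermutations),
                   function(i) sort(sample.int(n, n1)), integer(n1)))
    }
}

# delta-band cut points on the sorted observed d vs expected order stats
samCuts <- function(dsort, dbar, delta) {
    up <- which(dsort - dbar >= delta)
    lo <- which(dbar - dsort >= delta)
    list(cutup = if (length(up)) min(dsort[up]) else Inf,
         cutlow = if (length(lo)) max(dsort[lo]) else -Inf)
}

#' SAM differential expression with permutation FDR
#'
#' Two-class unpaired Significance Analysis of Microarrays. Per gene the
#' moderated difference statistic is \eqn{d = (\bar{x}_{PD} -
#' \bar{x}_{CT}) / (s + s_0)} with \eqn{s} the pooled standard error and
#' the fudge factor \eqn{s_0} chosen to minimize the coefficient of
#' variation of \eqn{d}'s spread across intensity windows. Expected
#' order statistics \eqn{\bar{d}_{(i)}} come from group-label
#' permutations (full enumeration when the number of label assignments
#' does not exceed \code{nPermutations}, otherwise random assignments
#' under \code{seed}). For each candidate delta, genes whose sorted
#' \eqn{d_{(i)}} deviates from \eqn{\bar{d}_{(i)}} by at least delta set
#' the upper/lower cut points; the FDR of that calling is the median
#' permutation count of statistics beyond the cuts, scaled by the
#' estimated true-null proportion \eqn{\hat\pi_0}, divided by the number
#' of genes called. The chosen delta is the smallest one whose
#' estimated FDR does not exceed \code{targetFDR}.
#'
#' @param study an \linkS4class{ExpressionStudy} containing both groups.
#' @param targetFDR target false discovery rate for the delta choice.
#' @param nPermutations permutation budget (>= 100 recommended; full
#'   enumeration is used automatically when it is at least the number of
#'   possible label assignments).
#' @param seed integer seed for the random permutations; fixed seed
#'   makes the call fully reproducible.
#' @return A \linkS4class{DEResult} with method \code{"sam"};
#'   \code{x@params} records \code{s0}, the chosen \code{delta}, the
#'   estimated \code{fdr} at that delta, \code{pi0} and the permutation
#'   count. If no delta calls a non-empty set at the target FDR, the
#'   significant set is empty, \code{delta} is \code{Inf} and a warning
#'   is raised.
#' @export
samDE <- function(study, targetFDR = 0.05, nPermutations = 200L, seed = 1L) {
    g <- sampleGroups(study)
    ct <- which(g == "CT"); pd <- which(g == "PD")
    if (length(ct) < 2 || length(pd) < 2)
        .stopf("samDE needs >= 2 samples per group (CT=%d, PD=%d)",
               length(ct), length(pd))
    x <- intensities(study)
    n <- ncol(x); n1 <- length(ct)

    obs0 <- samStatistics(x, ct, pd, 0)
    s0 <- chooseS0(obs0$r, obs0$s)
    d <- obs0$r / (obs0$s + s0)

    perms <- samPermutations(n, n1, nPermutations, seed)
    B <- ncol(perms)
    all_idx <- seq_len(n)
    dstar <- vapply(seq_len(B), function(b) {
        ctb <- perms[, b]
        samStatistics(x, ctb, setdiff(all_idx, ctb), s0)$d
    }, numeric(nrow(x)))
    dstar_sorted <- apply(dstar, 2, sort)
    dbar <- rowMeans(dstar_sorted)
    dsort <- sort(d)

    q <- stats::quantile(dstar, c(0.25, 0.75), names = FALSE)
    pi0 <- min(1, sum(d > q[1] & d < q[2]) / (0.5 * length(d)))

    deltas <- unique(c(0, stats::quantile(abs(dsort - dbar),
                                          seq(0, 1, length.out = 201),
                                          names = FALSE)))
    deltas <- sort(deltas)
    chosen <- NULL
    for (delta in deltas) {
        cuts <- samCuts(dsort, dbar, delta)
        called <- d >= cuts$cutup | d <= cuts$cutlow
        ncalled <- sum(called)
        if (ncalled == 0) break  # larger deltas call nothing either
        nfalse <- stats::median(colSums(dstar >= cuts$cutup) +
                                colSums(dstar <= cuts$cutlow))
        fdr <- min(1, pi0 * nfalse / ncalled)
        if (fdr <= targetFDR) {
            chosen <- list(delta = delta, fdr = fdr, called = called,
                           cuts = cuts)
            break
        }
    }

    if (is.null(chosen)) {
        warning(sprintf(
            "no delta reaches target FDR %.3g with a non-empty call set",
            targetFDR))
        chosen <- list(delta = Inf, fdr = NA_real_,
                       called = rep(FALSE, length(d)),
                       cuts = list(cutup = Inf, cutlow = -Inf))
    }

    tab <- data.frame(
        gene = rownames(x),
        statistic = unname(d),
        p_value = NA_real_,
        q_or_fdr = ifelse(chosen$called, chosen$fdr, NA_real_),
        direction = ifelse(obs0$r > 0, "up_in_case",
                    ifelse(obs0$r < 0, "down_in_case", NA_character_)),
        significant = unname(chosen$called),
        stringsAsFactors = FALSE)
    methods::new("DEResult", table = tab, method = "sam",
                 params = list(target_fdr = targetFDR, delta = chosen$delta,
                               fdr = chosen$fdr, s0 = s0, pi0 = pi0,
                               n_permutations = B, seed = seed,
                               cutup = chosen$cuts$cutup,
                               cutlow = chosen$cuts$cutlow))
}
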