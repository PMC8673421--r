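# Screen-side analysis: size-factor normalization, per-sgRNA enrichment
# statistics, and gene-level positive selection by alpha-truncated robust
# rank aggregation (RRA) with a permutation null. The RRA score of a gene
# with n sgRNAs at rank percentiles u_(1) <= ... <= u_(n) is
#   rho = min_{k : u_(k) <= alpha} P[Beta(k, n - k + 1) <= u_(k)],
# i.e. how surprisingly small the k-th best percentile is under uniform
# ranks, truncated to the top alpha fraction. Significance comes from
# permuted rank assignments of matched sgRNA-set size.

#' Median-of-ratios count normalization
#'
#' Computes per-sample size factors as the median ratio of a sample's
#' counts to the per-sgRNA geometric-mean reference, over sgRNAs with
#' all-positive counts; falls back to total-count scaling when fewer than
#' 100 sgRNAs qualify. Factors are rescaled to geometric mean 1, which makes
#' the operation idempotent.
#'
#' @param x A [screen_experiment] or a non-negative count matrix with at
#'   least 2 columns.
#' @return For a matrix: list with `mat` (scaled matrix), `size_factors`
#'   and `method`. For a `screen_experiment`: the same object with elements
#'   `norm`, `size_factors` and `norm_method` added.
#' @export
normalize_counts <- function(x) {
  UseMethod("normalize_counts")
}

#' @export
normalize_counts.matrix <- function(x) {
  stopifnot(ncol(x) >= 2, all(x >= 0))
  zero <- colSums(x) == 0
  if (any(zero)) {
    abort(paste0("All-zero sample(s): ",
                 paste(colnames(x)[zero], collapse = ", ")))
  }
  pos <- rowSums(x > 0) == ncol(x)
  if (sum(pos) >= 100) {
    ref <- exp(rowMeans(log(x[pos, , drop = FALSE])))
    sf <- apply(x[pos, , drop = FALSE] / ref, 2, median)
    method <- "median_of_ratios"
  } else if (sum(pos) >= 1) {
    ref <- exp(rowMeans(log(x[pos, , drop = FALSE])))
    sf <- apply(x[pos, , drop = FALSE] / ref, 2, median)
    method <- "median_of_ratios_small"
  } else {
    sf <- colSums(x)
    method <- "total_count"
  }
  sf <- sf / exp(mean(log(sf)))
  list(mat = sweep(x, 2, sf, "/"), size_factors = sf, method = method)
}

#' @export
normalize_counts.screen_experiment <- function(x) {
  norm <- normalize_counts(x$counts)
  x$norm <- norm$mat
  x$size_factors <- norm$size_factors
  x$norm_method <- norm$method
  x
}

#' Per-sgRNA enrichment statistics for one screened condition
#'
#' For the treated vs control arms of one condition, computes the log2 fold
#' change `lfc = log2((mean treated + pc) / (mean control + pc))` on
#' size-factor-normalized counts, a variance-stabilized enrichment score
#' (lfc standardized by a mean-variance trend fit across sgRNAs), and the
#' descending enrichment rank (ties averaged).
#'
#' @param x A [screen_experiment]; normalized on the fly if
#'   [normalize_counts()] has not been applied.
#' @param cell_line,drug,timepoint The condition to analyse.
#' @param pseudocount Added to both arm means. Default 0.5.
#' @return Tibble with columns `sgrna`, `gene`, `mean_control`,
#'   `mean_treated`, `lfc`, `score`, `rank`.
#' @export
sgrna_stats <- function(x, cell_line, drug, timepoint, pseudocount = 0.5) {
  stopifnot(inherits(x, "screen_experiment"))
  if (is.null(x$norm)) x <- normalize_counts(x)
  in_cond <- x$samples$cell_line == cell_line & x$samples$drug == drug &
    x$samples$timepoint == timepoint
  treated <- x$samples$sample[in_cond & x$samples$arm == "treated"]
  control <- x$samples$sample[in_cond & x$samples$arm == "control"]
  if (!length(treated) || !length(control)) {
    abort(paste0("Condition ", cell_line, "/", drug, "/d", timepoint,
                 " is missing a treated or control arm."))
  }
  mt <- rowMeans(x$norm[, treated, drop = FALSE])
  mc <- rowMeans(x$norm[, control, drop = FALSE])
  lfc <- log2((mt + pseudocount) / (mc + pseudocount))
  score <- stabilized_score(lfc, mc)
  tibble(
    sgrna = x$sgrna_map$sgrna,
    gene = x$sgrna_map$gene,
    mean_control = unname(mc),
    mean_treated = unname(mt),
    lfc = unname(lfc),
    score = unname(score),
    rank = rank(-score, ties.method = "average")
  )
}

# Standardize lfc by a lowess mean-variance trend over abundance; small
# inputs (< 50 sgRNAs) fall back to a pooled scale. Degenerate zero-variance
# input returns the lfc unchanged.
stabilized_score <- function(lfc, mean_control) {
  n <- length(lfc)
  if (n < 50) {
    s <- sd(lfc)
    if (!is.finite(s) || s == 0) return(lfc)
    return(lfc / s)
  }
  ab <- log2(mean_control + 0.5)
  fit <- lowess(ab, lfc^2, f = 0.5)
  v <- approx(fit$x, fit$y, xout = ab, rule = 2, ties = mean)$y
  floor_v <- max(1e-8, 0.01 * median(lfc^2))
  v <- pmax(v, floor_v)
  lfc / sqrt(v)
}

# rho for a matrix of row-sorted percentiles; rows with no percentile at or
# below alpha_frac score 1.
rra_rho <- function(u_sorted, alpha_frac) {
  if (is.null(dim(u_sorted))) u_sorted <- matrix(u_sorted, nrow = 1)
  s <- ncol(u_sorted)
  beta <- matrix(NA_real_, nrow(u_sorted), s)
  for (k in seq_len(s)) {
    beta[, k] <- pbeta(u_sorted[, k], k, s - k + 1)
  }
  beta[u_sorted > alpha_frac] <- Inf
  rho <- do.call(pmin, c(as.data.frame(beta), list(na.rm = FALSE)))
  rho[!is.finite(rho)] <- 1
  pmin(rho, 1)
}

rra_null <- function(N, s, n_perm, alpha_frac) {
  u <- matrix(NA_real_, n_perm, s)
  for (i in seq_len(n_perm)) {
    u[i, ] <- sort(sample.int(N, s)) / N
  }
  rra_rho(u, alpha_frac)
}

rra_exact_null <- function(N, s, alpha_frac) {
  sets <- combn(N, s)
  rra_rho(t(sets) / N, alpha_frac)
}

#' Gene-level positive selection by alpha-truncated rank aggregation
#'
#' Converts each gene's sgRNA enrichment ranks to percentiles `u = r / N`,
#' truncates to `u <= alpha_frac`, and scores the gene by the minimum
#' Beta(k, n - k + 1) lower-tail probability over the kept order statistics
#' (robust rank aggregation). Significance is a permutation p-value against
#' random rank sets of matched size, with add-one correction
#' `p = (1 + #\{rho_null <= rho_obs\}) / (1 + n_perm)`; when the number of
#' possible rank sets `choose(N, s)` does not exceed `n_perm` the null is
#' enumerated exhaustively and `p = #\{rho_null <= rho_obs\} / choose(N, s)`
#' is exact. The reported gene `lfc` averages the kept sgRNAs (all sgRNAs if
#' none are kept).
#'
#' @param stats Per-sgRNA tibble from [sgrna_stats()] (columns `gene`,
#'   `lfc`, `rank`).
#' @param alpha_frac Truncation fraction of top percentiles. Default 0.25.
#' @param n_perm Permutations per sgRNA-set size. Default 10000.
#' @param seed Integer seed for the permutation generator.
#' @param p_threshold Selection threshold. Default 0.05.
#' @return Tibble with one row per gene: `gene`, `n_sgrna`, `lfc`, `score`
#'   (rho), `p`, `rank` (ascending in rho, ties averaged), `selected`
#'   (`p < p_threshold` and `lfc > 0`).
#' @export
gene_rra <- function(stats, alpha_frac = 0.25, n_perm = 10000, seed = 1L,
                     p_threshold = 0.05) {
  stopifnot(is.data.frame(stats),
            all(c("gene", "lfc", "rank") %in% names(stats)),
            alpha_frac > 0, alpha_frac <= 1, n_perm >= 1)
  N <- nrow(stats)
  genes <- split(seq_len(N), stats$gene)
  sizes <- lengths(genes)
  empty <- sizes == 0
  if (any(empty)) {
    warn(paste0("Excluding gene(s) with zero sgRNAs: ",
                paste(names(genes)[empty], collapse = ", ")))
    genes <- genes[!empty]
    sizes <- sizes[!empty]
  }
  u_all <- stats$rank / N

  res <- withr::with_seed(seed, {
    purrr::map(sort(unique(sizes)), function(s) {
      idx <- genes[sizes == s]
      u <- matrix(vapply(idx, function(i) sort(u_all[i]), numeric(s)),
                  ncol = s, byrow = TRUE)
      rho <- rra_rho(u, alpha_frac)
      exact <- choose(N, s) <= n_perm
      null <- if (exact) rra_exact_null(N, s, alpha_frac)
              else rra_null(N, s, n_perm, alpha_frac)
      cnt <- findInterval(rho, sort(null))
      p <- if (exact) cnt / length(null) else (1 + cnt) / (1 + n_perm)
      lfc <- vapply(idx, function(i) {
        kept <- u_all[i] <= alpha_frac
        if (any(kept)) mean(stats$lfc[i][kept]) else mean(stats$lfc[i])
      }, numeric(1))
      tibble(gene = names(idx), n_sgrna = s, lfc = unname(lfc),
             score = rho, p = p)
    })
  })
  out <- bind_rows(res)
  out <- arrange(out, .data$score, .data$p, .data$gene)
  out$rank <- rank(out$score, ties.method = "average")
  out$selected <- out$p < p_threshold & out$lfc > 0
  out
}

#' Run RRA positive selection across all screened conditions
#'
#' Normalizes once, then for every (cell line, drug, timepoint) condition
#' with both arms computes per-sgRNA statistics and gene-level RRA results.
#'
#' @param x A [screen_experiment].
#' @inheritParams gene_rra
#' @param pseudocount Passed to [sgrna_stats()].
#' @return Tibble of per-condition gene results with `cell_line`, `drug`,
#'   `timepoint` columns prepended.
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_params(
#'   n_genes = 30, conditions = default_screen_conditions()[1, ],
#'   planted = planted_screen("G0001"), seed = 2))
#' res <- screen_rra(sim$screen, n_perm = 200, seed = 2)
#' head(dplyr::arrange(res, p))
screen_rra <- function(x, alpha_frac = 0.25, n_perm = 10000, seed = 1L,
                       p_threshold = 0.05, pseudocount = 0.5) {
  stopifnot(inherits(x, "screen_experiment"))
  x <- normalize_counts(x)
  conds <- distinct(x$samples[x$samples$arm == "treated",
                              c("cell_line", "drug", "timepoint")])
  purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    cond <- conds[i, ]
    st <- sgrna_stats(x, cond$cell_line, cond$drug, cond$timepoint,
                      pseudocount = pseudocount)
    res <- gene_rra(st, alpha_frac = alpha_frac, n_perm = n_perm,
                    seed = seed + i, p_threshold = p_threshold)
    dplyr::bind_cols(cond[rep(1, nrow(res)), ], res)
  })
}

#' Union of positively selected genes over all conditions
#'
#' @param results Per-condition gene results from [screen_rra()].
#' @param p_threshold Re-applied selection threshold (`p < p_threshold` and
#'   `lfc > 0`). Default 0.05.
#' @return A `screen_gene_set`: list with `members`, `support` (tibble of
#'   selected gene x condition rows), and `conditions`.
#' @export
screen_resistant_union <- function(results, p_threshold = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("gene", "cell_line", "drug", "timepoint", "p", "lfc",
                  "score") %in% names(results)))
  support <- filter(results, .data$p < p_threshold, .data$lfc > 0)
  structure(
    list(members = sort(unique(support$gene)),
         support = as_tibble(support),
         conditions = distinct(results[, c("cell_line", "drug",
                                           "timepoint")]),
         p_threshold = p_threshold),
    class = "screen_gene_set"
  )
}

cell_line_breakdown <- function(support, members, cell_lines) {
  by_gene <- support |>
    group_by(.data$gene) |>
    summarise(lines = list(sort(unique(.data$cell_line))), .groups = "drop")
  by_gene <- by_gene[by_gene$gene %in% members, ]
  grp <- vapply(by_gene$lines, function(l) {
    if (length(l) > 1) "multiple" else paste0(l, "_only")
  }, character(1))
  lvls <- c(paste0(sort(cell_lines), "_only"), "multiple")
  counts <- table(factor(grp, levels = lvls))
  tibble(group = names(counts), n = as.integer(counts),
         fraction = if (length(members)) as.integer(counts) / length(members)
                    else rep(NA_real_, length(counts)))
}

#' @export
print.screen_gene_set <- function(x, ...) {
  cat("<screen_gene_set> ", length(x$members),
      " genes positively selected in >= 1 of ", nrow(x$conditions),
      " conditions (p < ", x$p_threshold, ", lfc > 0)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.screen_gene_set <- function(x, ...) x$support

#' @exportS3Method generics::glance
glance.screen_gene_set <- function(x, ...) {
  bd <- cell_line_breakdown(x$support, x$members,
                            unique(x$conditions$cell_line))
  out <- tidyr::pivot_wider(bd[, c("group", "fraction")],
                            names_from = "group", values_from = "fraction",
                            names_prefix = "frac_")
  dplyr::bind_cols(tibble(n_members = length(x$members),
                          n_conditions = nrow(x$conditions)), out)
}

#' Top-quantile dual-cell-line consensus gene set
#'
#' Ranks the union-set genes by their best (minimum) RRA score across all
#' conditions, keeps the top `quantile` fraction (ties broken by smaller
#' best p, then gene symbol), and requires positive selection in at least
#' one condition of every screened cell line.
#'
#' @param results Per-condition gene results from [screen_rra()].
#' @param union_set A `screen_gene_set` from [screen_resistant_union()] or a
#'   character vector of genes.
#' @param quantile Fraction of the union retained by score. Default 0.25.
#' @return Tibble of consensus genes: `gene`, `best_score`, `best_p`,
#'   `n_conditions_selected`, `cell_lines`, ordered by rank.
#' @export
top_quantile_consensus <- function(results, union_set, quantile = 0.25) {
  stopifnot(quantile > 0, quantile <= 1)
  members <- if (inherits(union_set, "screen_gene_set")) union_set$members
             else as.character(union_set)
  if (!length(members)) return(consensus_empty())
  p_threshold <- if (inherits(union_set, "screen_gene_set")) {
    union_set$p_threshold
  } else 0.05
  per_gene <- results |>
    filter(.data$gene %in% members) |>
    group_by(.data$gene) |>
    summarise(
      best_score = min(.data$score),
      best_p = min(.data$p),
      n_conditions_selected = sum(.data$p < p_threshold & .data$lfc > 0),
      cell_lines = list(sort(unique(
        .data$cell_line[.data$p < p_threshold & .data$lfc > 0]))),
      .groups = "drop"
    ) |>
    arrange(.data$best_score, .data$best_p, .data$gene)
  n_keep <- ceiling(quantile * nrow(per_gene))
  top <- per_gene[seq_len(n_keep), ]
  all_lines <- sort(unique(results$cell_line))
  dual <- vapply(top$cell_lines, function(l) all(all_lines %in% l),
                 logical(1))
  out <- top[dual, ]
  out$cell_lines <- vapply(out$cell_lines, paste, character(1),
                           collapse = ",")
  out
}

consensus_empty <- function() {
  tibble(gene = character(0), best_score = numeric(0), best_p = numeric(0),
         n_conditions_selected = integer(0), cell_lines = character(0))
}
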