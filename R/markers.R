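#' Library-size normalize and log-transform a single-cell reference
#'
#' Fills the `logexpr` slot:
#' `logexpr[g, c] = log2(counts[g, c] * (median library size / library size of c) + pseudocount)`.
#' With the default pseudocount of 1 zeros stay zero, so sparse counts yield
#' sparse log expression.
#'
#' @param set A [cell_expression_set()].
#' @param pseudocount Added inside the log; default 1.
#' @return The set with `logexpr` computed.
#' @export
log_normalize <- function(set, pseudocount = 1) {
  stopifnot(inherits(set, "cell_expr_set"))
  lib <- Matrix::colSums(set$counts)
  if (any(lib == 0)) {
    stop(sum(lib == 0), " cell(s) have zero library size; remove them first",
         call. = FALSE)
  }
  sf <- median(lib) / lib
  norm <- scale_columns(set$counts, sf)
  set$logexpr <- if (pseudocount == 1 && inherits(norm, "sparseMatrix")) {
    norm@x <- log2(norm@x + 1)
    norm
  } else {
    log2(as.matrix(norm) + pseudocount)
  }
  set
}

# multiply column j of m by f[j], preserving sparsity
scale_columns <- function(m, f) {
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- m@x * rep.int(f, diff(m@p))
    m
  } else {
    sweep(m, 2, f, "*")
  }
}

# gene x type matrix of per-type mean expression; expr gene x cell.
# The dense path averages each group with rowMeans (extended-precision
# accumulation, same result as mean() per row); the sparse path uses an
# indicator-matrix product, which is far faster at single-cell scale.
group_means <- function(expr, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (!inherits(expr, "sparseMatrix")) {
    mm <- vapply(lev, function(g) {
      rowMeans(expr[, groups == g, drop = FALSE])
    }, numeric(nrow(expr)))
    mm <- matrix(mm, nrow = nrow(expr), dimnames = list(rownames(expr), lev))
    return(mm)
  }
  ind <- sparseMatrix(i = seq_along(groups),
                      j = match(groups, lev),
                      x = 1, dims = c(length(groups), length(lev)))
  n <- table(factor(groups, levels = lev))
  mm <- as.matrix(expr %*% ind)
  mm <- sweep(mm, 2, as.numeric(n), "/")
  colnames(mm) <- lev
  mm
}

#' Mean Ratio marker statistics
#'
#' For every gene and every target cell type, the Mean Ratio is the mean
#' expression of the gene in the target type divided by the *highest* mean
#' expression among the non-target types. A ratio above 1 means the gene is
#' expressed more in the target than in any other type; the larger the
#' ratio, the cleaner the marker. Unlike one-vs-all contrasts, which pool
#' the complement and so tolerate high expression in a single non-target
#' type, the Mean Ratio is penalised by the worst offender.
#'
#' Genes are ranked per target type by decreasing ratio (`rank_ratio`);
#' a mean ratio of `Inf` (perfectly specific gene: zero expression in every
#' non-target type) sorts before all finite ratios. Ties are broken by
#' higher target mean, then by gene id, so ranks are deterministic. A gene
#' with zero mean in the target *and* in all non-target types gets ratio 0.
#'
#' @param set A log-normalized [cell_expression_set()].
#' @param scale `"log"` (default) computes means on log-normalized
#'   expression; `"linear"` uses library-size-normalized counts.
#' @return A `marker_stats` tibble with columns `gene`, `cell_type`
#'   (the target), `mean_target`, `max_nontarget_mean`, `second_type`,
#'   `mean_ratio`, `rank_ratio`.
#' @export
#' @examples
#' ref <- log_normalize(simulate_reference(K = 3, G = 50, m = 5, D = 2,
#'                                         n_cells = 20, seed = 1)$reference)
#' mean_ratio_stats(ref)
mean_ratio_stats <- function(set, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  expr <- expression_matrix(set, scale)
  types <- unique(set$cell_meta$cell_type)
  if (length(types) < 2) {
    stop("at least two cell types are required", call. = FALSE)
  }
  mm <- group_means(expr, set$cell_meta$cell_type)
  types <- colnames(mm)
  per_target <- lapply(types, function(tt) {
    others <- mm[, setdiff(types, tt), drop = FALSE]
    j <- max.col(others, ties.method = "first")
    max_nt <- others[cbind(seq_len(nrow(others)), j)]
    ratio <- ifelse(mm[, tt] == 0 & max_nt == 0, 0, mm[, tt] / max_nt)
    tibble(
      gene = rownames(mm),
      cell_type = tt,
      mean_target = unname(mm[, tt]),
      max_nontarget_mean = unname(max_nt),
      second_type = colnames(others)[j],
      mean_ratio = unname(ratio)
    )
  })
  out <- bind_rows(per_target) %>%
    group_by(.data$cell_type) %>%
    mutate(rank_ratio = rank_desc(.data$mean_ratio, .data$mean_target,
                                  .data$gene)) %>%
    ungroup()
  new_marker_stats(out)
}

# deterministic 1-based descending rank: primary desc, tie desc mean, then id
rank_desc <- function(primary, tie_mean, id) {
  order(order(-primary, -tie_mean, id))
}

expression_matrix <- function(set, scale) {
  if (scale == "log") {
    if (is.null(set$logexpr)) {
      stop("logexpr not computed; call log_normalize() first", call. = FALSE)
    }
    set$logexpr
  } else {
    lib <- Matrix::colSums(set$counts)
    scale_columns(set$counts, median(lib) / lib)
  }
}

new_marker_stats <- function(df) {
  class(df) <- c("marker_stats", class(tibble()))
  df
}

#' One-vs-all marker statistics (Welch contrasts)
#'
#' The classic marker-finding contrast: for each target cell type, every
#' other cell is pooled into one complement group and each gene is tested
#' with a Welch two-sample t-test on log-normalized expression. Reported per
#' gene x target: the log fold change (difference of group means), the
#' standardized log fold change (logFC divided by the pooled standard
#' deviation, i.e. Cohen's d), the Welch t statistic and p-value, the
#' Benjamini-Hochberg FDR within the target type, and `rank_fc`, the
#' 1-based rank by decreasing standardized logFC.
#'
#' @param set A log-normalized [cell_expression_set()].
#' @param rank_by `"std_logfc"` (default) or `"logfc"`.
#' @return A `marker_stats` tibble with columns `gene`, `cell_type`,
#'   `mean_target`, `logfc`, `std_logfc`, `t_stat`, `p_value`, `fdr`,
#'   `rank_fc`.
#' @export
one_vs_all_stats <- function(set, rank_by = c("std_logfc", "logfc")) {
  rank_by <- match.arg(rank_by)
  if (is.null(set$logexpr)) {
    stop("logexpr not computed; call log_normalize() first", call. = FALSE)
  }
  expr <- set$logexpr
  groups <- set$cell_meta$cell_type
  types <- sort(unique(groups))
  if (length(types) < 2) stop("at least two cell types required", call. = FALSE)

  # sufficient statistics per type: n, sum, sum of squares per gene
  lev <- types
  ind <- sparseMatrix(i = seq_along(groups), j = match(groups, lev),
                      x = 1, dims = c(length(groups), length(lev)))
  n_k <- as.numeric(table(factor(groups, levels = lev)))
  s1 <- as.matrix(expr %*% ind)                 # gene x type sums
  s2 <- as.matrix((expr * expr) %*% ind)        # gene x type sums of squares
  n_tot <- sum(n_k)
  s1_tot <- rowSums(s1)
  s2_tot <- rowSums(s2)

  per_target <- lapply(seq_along(lev), function(k) {
    n1 <- n_k[k]
    n2 <- n_tot - n1
    if (n1 < 2 || n2 < 2) {
      stop("target '", lev[k], "' or its complement has fewer than 2 cells",
           call. = FALSE)
    }
    m1 <- s1[, k] / n1
    m2 <- (s1_tot - s1[, k]) / n2
    v1 <- pmax(0, (s2[, k] - n1 * m1^2) / (n1 - 1))
    v2 <- pmax(0, ((s2_tot - s2[, k]) - n2 * m2^2) / (n2 - 1))
    se2 <- v1 / n1 + v2 / n2
    lfc <- m1 - m2
    tt <- ifelse(se2 > 0, lfc / sqrt(se2),
                 ifelse(lfc == 0, 0, sign(lfc) * Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n_tot - 2)
    p <- 2 * pt(-abs(tt), df)
    pooled_sd <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n_tot - 2))
    d <- ifelse(pooled_sd > 0, lfc / pooled_sd,
                ifelse(lfc == 0, 0, sign(lfc) * Inf))
    tibble(
      gene = rownames(expr),
      cell_type = lev[k],
      mean_target = unname(m1),
      logfc = unname(lfc),
      std_logfc = unname(d),
      t_stat = unname(tt),
      p_value = unname(p),
      fdr = unname(p.adjust(p, method = "BH"))
    )
  })
  key <- if (rank_by == "std_logfc") "std_logfc" else "logfc"
  out <- bind_rows(per_target) %>%
    group_by(.data$cell_type) %>%
    mutate(rank_fc = rank_desc(.data[[key]], .data$mean_target,
                               .data$gene)) %>%
    ungroup()
  new_marker_stats(out)
}

#' Marker-set container
#'
#' @param sets Named list (per cell type) of ordered gene id vectors.
#' @param method Label, e.g. `"MeanRatio_top25"`.
#' @param universe Optional gene universe the sets were intersected with.
#' @return A `marker_set` object with per-type lists and their deduplicated
#'   union.
#' @export
marker_set <- function(sets, method, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(vapply(sets, anyDuplicated, 1L) > 0)) {
    stop("per-type marker lists must not contain duplicates", call. = FALSE)
  }
  structure(
    list(sets = sets, method = method,
         union = unique(unlist(sets, use.names = FALSE)),
         universe = universe),
    class = "marker_set"
  )
}

#' @exportS3Method base::print
print.marker_set <- function(x, ...) {
  sizes <- vapply(x$sets, length, 1L)
  cat("<marker_set> ", x$method, ": ", length(x$union),
      " genes in union\n  per type: ",
      paste0(names(sizes), "=", sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Top-N marker selection
#'
#' Takes, per cell type, the genes ranked 1..n by the chosen rank column and
#' *then* intersects with a gene universe (typically the genes shared with
#' the bulk dataset), preserving rank order. Because the intersection comes
#' after the cut, a type may contribute fewer than `n` genes.
#'
#' @param stats A `marker_stats` tibble.
#' @param rank_column `"rank_ratio"` (Mean Ratio) or `"rank_fc"` (1vALL).
#' @param n Genes per type before intersection.
#' @param universe Optional character vector of allowed gene ids; versioned
#'   ids are matched after stripping the version suffix.
#' @return A [marker_set()].
#' @export
select_top_n <- function(stats, rank_column = "rank_ratio", n = 25,
                         universe = NULL) {
  stopifnot(rank_column %in% names(stats))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  picked <- stats %>%
    filter(.data[[rank_column]] <= n) %>%
    arrange(.data$cell_type, .data[[rank_column]])
  sets <- split(picked$gene, picked$cell_type)
  sets <- apply_universe(sets, universe)
  label <- paste0(if (rank_column == "rank_ratio") "MeanRatio_top"
                  else "OneVsAll_top", n)
  marker_set(sets, label, universe)
}

#' Threshold-rule marker selection (Mean Ratio > threshold)
#'
#' Selects, per cell type, every gene whose Mean Ratio strictly exceeds the
#' threshold (default 2), preserving rank order. Infinite ratios are always
#' selected.
#'
#' @inheritParams select_top_n
#' @param threshold Strict lower bound on the mean ratio.
#' @return A [marker_set()].
#' @export
select_over_threshold <- function(stats, threshold = 2, universe = NULL) {
  stopifnot("mean_ratio" %in% names(stats))
  picked <- stats %>%
    filter(.data$mean_ratio > threshold) %>%
    arrange(.data$cell_type, .data$rank_ratio)
  sets <- split(picked$gene, picked$cell_type)
  sets <- fill_empty_types(sets, unique(stats$cell_type))
  sets <- apply_universe(sets, universe)
  marker_set(sets, paste0("MeanRatio_over", format(threshold)), universe)
}

#' Median + k MAD marker selection
#'
#' Adaptive per-type rule: restrict to genes with a finite Mean Ratio
#' strictly above 1 (genes at least nominally specific), compute the median
#' and the MAD (scaled by the normal-consistency constant 1.4826) of those
#' ratios, and select the genes whose ratio strictly exceeds
#' `median + k * MAD`. Infinite ratios are always selected. Types with fewer
#' than two finite ratios above 1 contribute an empty set with a warning.
#'
#' @inheritParams select_top_n
#' @param k Number of MADs above the median (default 3).
#' @param mad_constant Scale constant for the MAD; 1.4826 makes the MAD a
#'   consistent estimator of the standard deviation under normality.
#' @return A [marker_set()].
#' @export
#' @examples
#' # hand-checkable: ratios > 1 are {1.2, 1.5, 2, 3, 10}; median 2,
#' # raw MAD 0.8, threshold 2 + 3 * 1.4826 * 0.8 = 5.558 -> only 10 passes
select_mad_rule <- function(stats, k = 3, universe = NULL,
                            mad_constant = 1.4826) {
  stopifnot("mean_ratio" %in% names(stats))
  types <- unique(stats$cell_type)
  sets <- lapply(setNames(types, types), function(tt) {
    sub <- stats %>%
      filter(.data$cell_type == tt) %>%
      arrange(.data$rank_ratio)
    finite_gt1 <- sub$mean_ratio[is.finite(sub$mean_ratio) &
                                   sub$mean_ratio > 1]
    if (length(finite_gt1) < 2) {
      warning("type '", tt, "' has fewer than 2 finite ratios > 1; ",
              "contributes no genes", call. = FALSE)
      return(sub$gene[is.infinite(sub$mean_ratio)])
    }
    thr <- median(finite_gt1) +
      k * mad(finite_gt1, constant = mad_constant)
    sub$gene[is.infinite(sub$mean_ratio) |
               (sub$mean_ratio > 1 & sub$mean_ratio > thr)]
  })
  sets <- apply_universe(sets, universe)
  marker_set(sets, paste0("MeanRatio_MAD", format(k)), universe)
}

apply_universe <- function(sets, universe) {
  if (is.null(universe)) return(sets)
  uni <- strip_gene_version(universe)
  out <- lapply(sets, function(g) g[strip_gene_version(g) %in% uni])
  if (all(vapply(out, length, 1L) == 0)) {
    warning("marker sets are empty after intersecting with the universe",
            call. = FALSE)
  }
  out
}

fill_empty_types <- function(sets, types) {
  for (tt in setdiff(types, names(sets))) sets[[tt]] <- character(0)
  sets[sort(names(sets))]
}

#' Highly variable gene selection
#'
#' Ranks genes by the residual of their log-expression variance above a
#' running-median mean-variance trend and returns the top fraction `prop` of
#' positive-residual genes. This is a deliberately simple variance model --
#' adequate as plumbing for marker-set sweeps, not a replacement for a full
#' variance-decomposition method.
#'
#' Selections nest: the genes chosen at `prop = 0.1` are a subset of those
#' chosen at `prop = 0.2`.
#'
#' @param set A log-normalized [cell_expression_set()].
#' @param prop Fraction of positive-residual genes to return, in (0, 1].
#' @return Character vector of gene ids ordered by decreasing residual.
#' @export
select_hvg <- function(set, prop = 0.1) {
  if (!is.numeric(prop) || prop <= 0 || prop > 1) {
    stop("`prop` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(set$logexpr)) {
    stop("logexpr not computed; call log_normalize() first", call. = FALSE)
  }
  expr <- set$logexpr
  n <- ncol(expr)
  mu <- Matrix::rowSums(expr) / n
  ex2 <- Matrix::rowSums(expr * expr) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  ord <- order(mu)
  k <- min(length(mu), max(3L, 2L * floor(length(mu) * 0.05) + 1L))
  trend <- numeric(length(mu))
  trend[ord] <- runmed(v[ord], k, endrule = "median")
  resid <- v - trend
  pos <- which(resid > 0)
  pos <- pos[order(-resid[pos], rownames(expr)[pos])]
  head(rownames(expr)[pos], ceiling(prop * length(pos)))
}

#' Serialize marker statistics or sets to TSV
#'
#' @param x A `marker_stats` tibble or [marker_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(x, path) {
  if (inherits(x, "marker_set")) x <- tidy(x)
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
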