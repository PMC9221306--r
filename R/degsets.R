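# Post-differential-expression set analytics. DE tables are consumed as
# produced upstream (per-gene log2 fold change, raw p, BH FDR per
# contrast); this module selects direction-consistent genes across
# replicate strains, partitions sets Venn-style, and scores flat gene-set
# annotations by one-sided Fisher enrichment with the dot-plot metrics
# (mean logFC of significant term genes, proportion of the term altered).

#' Read a differential-expression result table (TSV)
#'
#' Expected header: `gene_id`, `logFC`, `PValue`, `FDR` (tab-separated,
#' one file per strain-vs-control contrast).
#'
#' @param path Path to the TSV file.
#' @param contrast Optional contrast label stored as an attribute.
#' @return A tibble with columns `gene_id`, `logFC`, `PValue`, `FDR`.
#' @export
read_de_table <- function(path, contrast = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character"))
  need <- c("gene_id", "logFC", "PValue", "FDR")
  if (!identical(names(df), need)) {
    stop("malformed DE header: expected ", paste(need, collapse = "\t"),
         call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in ", path, call. = FALSE)
  }
  if (any(!is.finite(df$logFC))) stop("non-finite logFC in ", path,
                                      call. = FALSE)
  if (any(df$FDR < 0 | df$FDR > 1, na.rm = TRUE)) {
    stop("FDR outside [0, 1] in ", path, call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "contrast") <- contrast
  out
}

#' Write a DE table in the package TSV dialect
#' @param table Tibble with `gene_id`, `logFC`, `PValue`, `FDR`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(as.data.frame(table)[c("gene_id", "logFC", "PValue",
                                            "FDR")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat gene-to-term annotation (TSV)
#'
#' Expected columns: `gene_id`, `term_id` and optionally `term_name`. The
#' annotation is taken as a flat map; no ontology-graph propagation is
#' performed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id`, `term_id` (and `term_name` if present).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    stop("annotation must have gene_id and term_id columns", call. = FALSE)
  }
  tibble::as_tibble(df)
}

# annotation -> named list term_id -> character vector of gene ids
.as_term_list <- function(annotation) {
  if (is.list(annotation) && !is.data.frame(annotation)) {
    if (is.null(names(annotation)) || any(names(annotation) == "")) {
      stop("annotation list must be named by term_id", call. = FALSE)
    }
    return(lapply(annotation, unique))
  }
  split(annotation$gene_id, annotation$term_id)
}

#' Select significant genes from one DE table
#'
#' Genes with `FDR < fdr_threshold` whose fold-change sign matches
#' `direction` (`"down"`: logFC < 0; `"up"`: logFC > 0; `"any"`: either).
#'
#' @param table DE tibble (see [read_de_table()]).
#' @param fdr_threshold FDR cutoff in `(0, 1)` (default 0.05).
#' @param direction `"any"`, `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(table, fdr_threshold = 0.05,
                              direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0, 1)", call. = FALSE)
  }
  keep <- table$FDR < fdr_threshold
  keep <- keep & switch(direction,
                        any = TRUE,
                        up = table$logFC > 0,
                        down = table$logFC < 0)
  table$gene_id[keep & !is.na(keep)]
}

#' Direction-consistent genes across replicate contrasts
#'
#' Operationalizes "similar pattern of expression changes" across replicate
#' deletion strains. Strict mode (default): the gene is significant in
#' every table and its fold-change sign agrees across all tables. Lenient
#' mode: the gene is present in every table with concordant sign and
#' significant in at least one. Genes absent from any table are excluded
#' (treated as not significant there) and counted in a message.
#'
#' @param tables List of at least two DE tibbles.
#' @inheritParams significant_genes
#' @param mode `"strict"` or `"lenient"`.
#' @return Character vector of gene ids.
#' @export
consistent_genes <- function(tables, fdr_threshold = 0.05,
                             direction = c("any", "up", "down"),
                             mode = c("strict", "lenient")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (length(tables) < 2L) stop("need at least two DE tables", call. = FALSE)
  shared <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  n_dropped <- length(Reduce(union, lapply(tables, function(t) t$gene_id))) -
    length(shared)
  if (n_dropped > 0L) {
    message(sprintf("consistent_genes: %d gene(s) absent from at least one table treated as not significant there",
                    n_dropped))
  }
  sig <- lapply(tables, significant_genes, fdr_threshold = fdr_threshold,
                direction = "any")
  signs <- vapply(tables, function(t) {
    sign(t$logFC[match(shared, t$gene_id)])
  }, numeric(length(shared)))
  signs <- matrix(signs, nrow = length(shared))
  concordant <- shared[apply(signs, 1L, function(s) {
    all(s == s[1L]) && s[1L] != 0
  })]
  genes <- switch(mode,
                  strict = Reduce(intersect, c(list(concordant), sig)),
                  lenient = intersect(concordant, Reduce(union, sig)))
  if (direction != "any") {
    s1 <- sign(tables[[1L]]$logFC[match(genes, tables[[1L]]$gene_id)])
    genes <- genes[if (direction == "down") s1 < 0 else s1 > 0]
  }
  genes
}

#' Venn partition of named gene sets
#'
#' Partitions the union of 1-4 named sets into its `2^k - 1` disjoint
#' membership regions and counts each. Region labels join set names with
#' `&` (e.g. `"A&B"` is the region in A and B but no other set).
#'
#' @param named_sets Named list of character vectors.
#' @return A tibble with `region` (label), `sets` (list of member set
#'   names) and `count`; regions are pairwise disjoint and their counts
#'   sum to the size of the union.
#' @export
venn_partition <- function(named_sets) {
  k <- length(named_sets)
  if (k < 1L || k > 4L) stop("need between 1 and 4 named sets", call. = FALSE)
  if (is.null(names(named_sets)) || any(names(named_sets) == "")) {
    stop("sets must be named", call. = FALSE)
  }
  nm <- names(named_sets)
  universe <- unique(unlist(named_sets, use.names = FALSE))
  member <- vapply(named_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  # all non-empty membership signatures, ordered by region size then name
  sigs <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  rows <- lapply(seq_len(nrow(sigs)), function(i) {
    sig <- as.logical(sigs[i, ])
    inside <- if (length(universe)) {
      apply(member, 1L, function(m) all(m == sig))
    } else {
      logical(0)
    }
    tibble::tibble(region = paste(nm[sig], collapse = "&"),
                   sets = list(nm[sig]), count = sum(inside))
  })
  out <- do.call(rbind, rows)
  out[order(lengths(out$sets), out$region), ]
}

#' One-sided Fisher gene-set enrichment
#'
#' For each term, tests over-representation of the study set in the term
#' with the one-sided Fisher exact probability of the 2x2 table
#' `(k, K - k, n - k, N - K - n + k)` — the hypergeometric upper tail
#' `P(X >= k)` with `K` term genes among `N` universe genes and a study
#' set of size `n`. P-values are BH-adjusted across terms. When a DE table
#' is supplied, each row also carries the dot-plot metrics: the mean logFC
#' over the term's significant genes and the proportion of the term
#' altered (see [term_dot_metrics()]).
#'
#' @param study_set Character vector of gene ids (restricted to the
#'   universe; genes outside it are dropped with a message).
#' @param annotation Flat annotation: tibble with `gene_id`/`term_id` or a
#'   named list term -> genes.
#' @param universe Character vector of background gene ids. Default: all
#'   genes of `de_table` when given (expressed-gene background), otherwise
#'   the union of annotated genes and the study set.
#' @param fdr_threshold Significance cutoff used for the dot-plot metrics.
#' @param de_table Optional DE tibble providing logFC/FDR for the metrics.
#' @return A tibble with one row per term: `term_id`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `mean_logfc`, `prop_altered`, ordered by `p`. Terms with no
#'   universe genes are dropped with a message.
#' @export
fisher_enrichment <- function(study_set, annotation, universe = NULL,
                              fdr_threshold = 0.05, de_table = NULL) {
  terms <- .as_term_list(annotation)
  if (is.null(universe)) {
    universe <- if (!is.null(de_table)) {
      de_table$gene_id
    } else {
      union(unique(unlist(terms, use.names = FALSE)), study_set)
    }
  }
  universe <- unique(universe)
  outside <- setdiff(study_set, universe)
  if (length(outside)) {
    message(sprintf("fisher_enrichment: %d study gene(s) outside the universe dropped",
                    length(outside)))
  }
  study_set <- unique(intersect(study_set, universe))
  n <- length(study_set)
  n_univ <- length(universe)
  term_genes <- lapply(terms, intersect, universe)
  empty <- lengths(term_genes) == 0L
  if (any(empty)) {
    message(sprintf("fisher_enrichment: %d term(s) empty after universe restriction dropped",
                    sum(empty)))
    term_genes <- term_genes[!empty]
  }
  if (length(term_genes) == 0L) {
    return(tibble::tibble(term_id = character(), k = integer(),
                          K = integer(), n = integer(), N = integer(),
                          p = double(), q = double(), mean_logfc = double(),
                          prop_altered = double()))
  }
  big_k <- unname(lengths(term_genes))
  k <- vapply(term_genes, function(g) length(intersect(g, study_set)),
              integer(1L), USE.NAMES = FALSE)
  p <- stats::phyper(k - 1, big_k, n_univ - big_k, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(term_id = names(term_genes), k = as.integer(k),
                        K = as.integer(big_k), n = as.integer(n),
                        N = as.integer(n_univ), p = p, q = q,
                        mean_logfc = NA_real_, prop_altered = NA_real_)
  if (!is.null(de_table)) {
    metrics <- term_dot_metrics(de_table, term_genes,
                                fdr_threshold = fdr_threshold)
    i <- match(out$term_id, metrics$term_id)
    out$mean_logfc <- metrics$mean_logfc[i]
    out$prop_altered <- metrics$prop_altered[i]
  }
  out[order(out$p, out$term_id), ]
}

#' Per-term dot-plot metrics: mean logFC and proportion altered
#'
#' For each annotation term: the mean log2 fold change over the term's
#' genes that pass the FDR cutoff in the DE table (NA when no term gene is
#' significant — the colour of the dot), and the proportion of the term's
#' genes with altered expression, `(# term genes with FDR < threshold) /
#' (term size)` — the size of the dot.
#'
#' @param table DE tibble with `gene_id`, `logFC`, `FDR`.
#' @param annotation Flat annotation (tibble or named list).
#' @inheritParams significant_genes
#' @return A tibble with `term_id`, `K` (term size among table genes),
#'   `n_sig`, `mean_logfc`, `prop_altered`.
#' @export
term_dot_metrics <- function(table, annotation, fdr_threshold = 0.05) {
  terms <- .as_term_list(annotation)
  sig <- significant_genes(table, fdr_threshold = fdr_threshold,
                           direction = "any")
  rows <- lapply(names(terms), function(tid) {
    g <- intersect(terms[[tid]], table$gene_id)
    if (length(g) == 0L) {
      return(tibble::tibble(term_id = tid, K = 0L, n_sig = 0L,
                            mean_logfc = NA_real_, prop_altered = NA_real_))
    }
    gs <- intersect(g, sig)
    tibble::tibble(term_id = tid, K = length(g), n_sig = length(gs),
                   mean_logfc = if (length(gs)) {
                     mean(table$logFC[match(gs, table$gene_id)])
                   } else {
                     NA_real_
                   },
                   prop_altered = length(gs) / length(g))
  })
  do.call(rbind, rows)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target transcript in a sample relative to a control
#' condition, each normalized to a housekeeping reference gene:
#' `fold = 2^-ddCt` with
#' `ddCt = (Ct_target_sample - Ct_ref_sample) - (Ct_target_control -
#' Ct_ref_control)`. Vector inputs are averaged (replicate Ct values).
#'
#' @param ct_target_sample,ct_ref_sample Ct values of target and reference
#'   gene in the sample of interest.
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition.
#' @return The fold change (1 = no change).
#' @examples
#' ddct_fold_change(22, 18, 20, 18)  # ddCt = 2 -> 0.25
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_control,
            ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (mean(ct_target_sample) - mean(ct_ref_sample)) -
    (mean(ct_target_control) - mean(ct_ref_control))
  2^(-ddct)
}
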