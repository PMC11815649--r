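#' @importFrom stats median hclust cutree kmeans dist
NULL

# Stage columns = numeric columns that are not identifiers or diagnostics.
.stage_cols <- function(df) {
  meta <- c("scan", "charge", "n_matched", "cluster", "n_peptides",
            "total_sn", "residual", "n_oxidation", "precursor_mz",
            "xcorr", "delta_cn", "ppm_dev")
  names(df)[vapply(df, is.numeric, logical(1)) & !names(df) %in% meta]
}

#' Razor assignment of shared peptides to proteins
#'
#' Peptides matching a single protein are assigned directly; peptides
#' matching several candidates are assigned to the candidate with the most
#' unique peptides, with a deterministic lexicographic tie-break.
#'
#' @param psms Tibble with columns `peptide` and `protein`; a peptide's
#'   candidate proteins are given either as repeated rows or as a single
#'   `;`-separated string.
#' @return Tibble: `peptide`, `protein` (assigned), `shared`, `tie`.
#' @export
assign_peptides_to_proteins <- function(psms) {
  if (any(is.na(psms$protein) | psms$protein == "")) {
    abort("Peptide with no candidate protein.")
  }
  pairs <- psms |>
    select("peptide", "protein") |>
    mutate(protein = strsplit(.data$protein, ";", fixed = TRUE)) |>
    tidyr::unnest("protein") |>
    dplyr::distinct()
  cand_count <- pairs |> group_by(.data$peptide) |> summarise(n_cand = n())
  unique_counts <- pairs |>
    left_join(cand_count, by = "peptide") |>
    filter(.data$n_cand == 1) |>
    group_by(.data$protein) |>
    summarise(n_unique = n(), .groups = "drop")
  pairs |>
    left_join(cand_count, by = "peptide") |>
    left_join(unique_counts, by = "protein") |>
    mutate(n_unique = tidyr::replace_na(.data$n_unique, 0L)) |>
    group_by(.data$peptide) |>
    arrange(dplyr::desc(.data$n_unique), .data$protein, .by_group = TRUE) |>
    summarise(
      protein = .data$protein[1],
      shared = n() > 1,
      tie = n() > 1 && sum(.data$n_unique == max(.data$n_unique)) > 1,
      .groups = "drop"
    )
}

#' Normalize stage columns to an anchor peptide set
#'
#' Scales each stage column so the aggregated (summed by default, median
#' optionally) signal of anchor peptides -- the mitochondrial-protein
#' stand-in -- is constant across the time course, preserved at its
#' pre-normalization mean.
#'
#' @param quant Peptide tibble with a `peptide` column and numeric stage
#'   columns; anchors identified by a logical `anchor` column or via
#'   `anchor_ids`.
#' @param anchor_ids Optional character vector of anchor peptide ids.
#' @param stat Aggregation across anchor peptides: `"sum"` (default) or
#'   `"median"`.
#' @return The tibble with rescaled stage columns.
#' @export
normalize_to_anchor <- function(quant, anchor_ids = NULL,
                                stat = c("sum", "median")) {
  stat <- match.arg(stat)
  agg <- if (stat == "sum") sum else median
  is_anchor <- if (!is.null(anchor_ids)) {
    quant$peptide %in% anchor_ids
  } else if ("anchor" %in% names(quant)) {
    quant$anchor
  } else {
    abort("Provide `anchor_ids` or an `anchor` column.")
  }
  if (!any(is_anchor)) abort("No anchor peptides found.")
  cols <- .stage_cols(quant)
  anchor_level <- vapply(cols, function(cn) agg(quant[[cn]][is_anchor]), numeric(1))
  if (any(anchor_level <= 0)) {
    abort(paste0("Zero anchor signal in column(s): ",
                 paste(cols[anchor_level <= 0], collapse = ", ")))
  }
  target <- mean(anchor_level)
  for (cn in cols) quant[[cn]] <- quant[[cn]] * target / anchor_level[[cn]]
  quant
}

#' Roll peptides up to protein-level profiles
#'
#' For each protein: every peptide profile is scaled to its own mean, the
#' per-stage median across peptides is taken (the "median-corrected signal"),
#' and the result is rescaled so the protein's summed signal equals its
#' peptides' total signal. Proteins with zero quantified signal are dropped
#' with a message.
#'
#' @param quant Normalized peptide tibble (columns `peptide`, `protein`,
#'   stages).
#' @param assignment Optional razor assignment from
#'   [assign_peptides_to_proteins()]; when given, it overrides the `protein`
#'   column.
#' @param center Per-peptide scaling statistic before the median:
#'   `"mean"` (default) or `"none"`.
#' @return Protein-level tibble: `protein`, `n_peptides`, stage columns.
#' @export
rollup_proteins <- function(quant, assignment = NULL,
                            center = c("mean", "none")) {
  center <- match.arg(center)
  if (!is.null(assignment)) {
    quant <- quant |>
      select(-dplyr::any_of("protein")) |>
      left_join(assignment |> select("peptide", "protein"), by = "peptide")
  }
  cols <- setdiff(.stage_cols(quant), character(0))
  dropped <- quant |>
    group_by(.data$protein) |>
    summarise(tot = sum(dplyr::pick(dplyr::all_of(cols))), .groups = "drop") |>
    filter(.data$tot <= 0)
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " protein(s) with zero quantified signal dropped.")
    quant <- quant |> filter(!.data$protein %in% dropped$protein)
  }
  quant |>
    group_by(.data$protein) |>
    dplyr::group_modify(function(df, key) {
      m <- as.matrix(df[, cols])
      total <- sum(m)
      if (center == "mean") m <- m / rowMeans(m)
      med <- apply(m, 2, median)
      out <- med * total / sum(med)
      res <- tibble(n_peptides = nrow(df))
      for (i in seq_along(cols)) res[[cols[i]]] <- out[i]
      res
    }) |>
    ungroup()
}

#' Hierarchical k-means clustering of protein trajectories
#'
#' Rows are first normalized to fractional profiles (each protein summing to
#' 1) so clusters reflect trajectory shape rather than abundance. Cluster
#' centers are initialized from a Ward-linkage hierarchical cut at `k`, then
#' refined with standard Lloyd k-means iterations -- deterministic given the
#' input order.
#'
#' @param protein_quant Protein tibble (`protein` + stage columns).
#' @param k Number of clusters (1 <= k <= number of proteins).
#' @param row_normalize Normalize rows to fractions first (default `TRUE`).
#' @param iter_max Maximum Lloyd iterations (default 100).
#' @return Object of class `hkmeans_fit` with `clusters` (tibble `protein`,
#'   `cluster`), `centers`, `k`, `tot_withinss` and the (normalized) data.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
hkmeans_cluster <- function(protein_quant, k, row_normalize = TRUE,
                            iter_max = 100) {
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(protein_quant)) abort("`k` exceeds the number of proteins.")
  cols <- .stage_cols(protein_quant)
  m <- as.matrix(protein_quant[, cols])
  rownames(m) <- protein_quant$protein
  if (row_normalize) m <- m / rowSums(m)
  if (k == 1) {
    km <- list(cluster = stats::setNames(rep(1L, nrow(m)), rownames(m)),
               centers = matrix(colMeans(m), 1, dimnames = list(NULL, cols)),
               tot.withinss = sum(sweep(m, 2, colMeans(m))^2))
  } else {
    hc <- hclust(dist(m), method = "ward.D2")
    init <- cutree(hc, k = k)
    centers <- do.call(rbind, lapply(seq_len(k), function(g) {
      colMeans(m[init == g, , drop = FALSE])
    }))
    km <- kmeans(m, centers = centers, iter.max = iter_max,
                 algorithm = "Lloyd")
  }
  structure(list(
    clusters = tibble(protein = rownames(m), cluster = unname(km$cluster)),
    centers = km$centers,
    k = k,
    tot_withinss = km$tot.withinss,
    data = m
  ), class = "hkmeans_fit")
}

#' @export
print.hkmeans_fit <- function(x, ...) {
  cat("<hkmeans_fit> k =", x$k, "on", nrow(x$data), "proteins;",
      "total within-SS", format(x$tot_withinss, digits = 4), "\n")
  print(table(x$clusters$cluster))
  invisible(x)
}

#' @rdname hkmeans_cluster
#' @param x An `hkmeans_fit`.
#' @param ... Unused.
#' @export
tidy.hkmeans_fit <- function(x, ...) x$clusters

#' @rdname hkmeans_cluster
#' @export
glance.hkmeans_fit <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$data), tot_withinss = x$tot_withinss)
}

#' Two-pass reclustering schedule
#'
#' Clusters at `k_first`, isolates one designated cluster (for example the
#' maternally deposited class), then reclusters the remaining proteins at
#' `k_second`. Isolated proteins get cluster label 0.
#'
#' @param protein_quant Protein tibble.
#' @param k_first,k_second Cluster counts of the two passes (e.g. 10 then 5).
#' @param isolate Which first-pass cluster to set aside: an integer label or
#'   a function of the first-pass center matrix returning one.
#' @param ... Passed to [hkmeans_cluster()].
#' @return Tibble `protein`, `cluster` (0 = isolated), plus both fits as
#'   attributes.
#' @export
recluster_schedule <- function(protein_quant, k_first = 10, k_second = 5,
                               isolate = function(centers) {
                                 which.max(centers[, 1] - centers[, ncol(centers)])
                               }, ...) {
  fit1 <- hkmeans_cluster(protein_quant, k_first, ...)
  iso <- if (is.function(isolate)) isolate(fit1$centers) else isolate
  iso_prot <- fit1$clusters$protein[fit1$clusters$cluster == iso]
  rest <- protein_quant |> filter(!.data$protein %in% iso_prot)
  fit2 <- hkmeans_cluster(rest, k_second, ...)
  out <- bind_rows(
    tibble(protein = iso_prot, cluster = 0L),
    fit2$clusters
  )
  attr(out, "first_pass") <- fit1
  attr(out, "second_pass") <- fit2
  out
}

#' First-to-last fold-change summary
#'
#' Per-protein log2 ratio between the first and last stage, and the
#' fractions of proteins decreasing or increasing by more than
#' `threshold_fold`. Zeros are floored at half the smallest positive value
#' in the matrix and flagged.
#'
#' @param protein_quant Protein tibble (`protein` + stage columns, first and
#'   last columns used).
#' @param threshold_fold Fold-change threshold (> 1; default 2).
#' @return Object of class `fold_change_summary`; `tidy()` returns the
#'   per-protein table, `glance()` the fractions (decreasing + increasing +
#'   within = 1).
#' @export
fold_change_summary <- function(protein_quant, threshold_fold = 2) {
  if (threshold_fold <= 1) abort("`threshold_fold` must be > 1.")
  cols <- .stage_cols(protein_quant)
  first <- protein_quant[[cols[1]]]
  last <- protein_quant[[cols[length(cols)]]]
  pos <- c(first[first > 0], last[last > 0])
  floor_val <- if (length(pos)) min(pos) * 0.5 else 1
  floored <- first <= 0 | last <= 0
  ratio <- log2(pmax(first, floor_val) / pmax(last, floor_val))
  thr <- log2(threshold_fold)
  tab <- tibble(
    protein = protein_quant$protein,
    log2_first_last = ratio,
    floored = floored,
    class = dplyr::case_when(
      ratio > thr ~ "decreasing",
      ratio < -thr ~ "increasing",
      TRUE ~ "within"
    )
  )
  structure(list(
    table = tab,
    threshold_fold = threshold_fold,
    fractions = c(
      decreasing = mean(tab$class == "decreasing"),
      increasing = mean(tab$class == "increasing"),
      within = mean(tab$class == "within")
    )
  ), class = "fold_change_summary")
}

#' @export
print.fold_change_summary <- function(x, ...) {
  cat("<fold_change_summary> threshold", x$threshold_fold, "fold\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' @rdname fold_change_summary
#' @param x A `fold_change_summary`.
#' @param ... Unused.
#' @export
tidy.fold_change_summary <- function(x, ...) x$table

#' @rdname fold_change_summary
#' @export
glance.fold_change_summary <- function(x, ...) {
  tibble(threshold_fold = x$threshold_fold,
         frac_decreasing = x$fractions[["decreasing"]],
         frac_increasing = x$fractions[["increasing"]],
         frac_within = x$fractions[["within"]])
}

#' Orthogroup representative selection
#'
#' When several proteins of an orthogroup are detected in one organism, the
#' protein with the most quantified peptides represents the orthogroup;
#' ties break lexicographically. Proteins absent from the quantification
#' results are ignored with a message.
#'
#' @param orthogroups Tibble `orthogroup_id`, `organism`, `protein_id`
#'   (external ortholog-inference output, consumed as TSV).
#' @param peptide_counts Tibble `protein_id`, `n_peptides` (quantified
#'   peptide counts).
#' @return Tibble with one representative per (orthogroup, organism):
#'   `orthogroup_id`, `organism`, `protein_id`, `n_peptides`, `tie`.
#' @export
orthogroup_representatives <- function(orthogroups, peptide_counts) {
  known <- orthogroups$protein_id %in% peptide_counts$protein_id
  if (any(!known)) {
    message(sum(!known), " orthogroup protein(s) absent from quantification ignored.")
  }
  orthogroups |>
    filter(known) |>
    left_join(peptide_counts, by = "protein_id") |>
    group_by(.data$orthogroup_id, .data$organism) |>
    arrange(dplyr::desc(.data$n_peptides), .data$protein_id, .by_group = TRUE) |>
    summarise(
      tie = n() > 1 && sum(.data$n_peptides == max(.data$n_peptides)) > 1,
      protein_id = .data$protein_id[1],
      n_peptides = .data$n_peptides[1],
      .groups = "drop"
    ) |>
    select("orthogroup_id", "organism", "protein_id", "n_peptides", "tie")
}
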