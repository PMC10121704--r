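#' Default analysis parameters ("study mode")
#'
#' Every printed parameter of the emulated study in one list: the 100-UMI
#' droplet pre-filter, the per-type QC gates, clustering resolutions 0.5
#' (full dataset) and 0.2 (subtypes), 17/16 principal components, marker
#' thresholds (10% expressing, log2FC > 0.25), DE thresholds (p_adj < 0.05,
#' |log2FC| > 1), the 10-800 GSEA set-size window with 1000 permutations, the
#' 5-um Sholl geometry and the 20-frame brightest substack.
#' @return named list of defaults; override entries and pass to the pipeline
#'   runners.
#' @export
default_parameters <- function() {
  list(
    min_umi = 100,
    qc_thresholds = celltype_qc_thresholds(),
    scale_factor = 10000,
    n_hvg = 2000,
    scale_cap = 10,
    n_pcs = 17,
    n_pcs_subtype = 16,
    k_neighbors = 20,
    resolution = 0.5,
    resolution_subtype = 0.2,
    min_expressing = 0.80,
    marker_min_pct = 0.10,
    marker_min_log2fc = 0.25,
    de_alpha = 0.05,
    de_lfc = 1,
    gsea_min_size = 10,
    gsea_max_size = 800,
    gsea_n_perm = 1000,
    sholl_r_start = 5,
    sholl_r_step = 5,
    n_brightest_frames = 20,
    seed = 1L
  )
}

merge_params <- function(params) {
  base <- default_parameters()
  if (is.null(params)) return(base)
  unknown <- setdiff(names(params), names(base))
  stop_if_not(length(unknown) == 0, "unknown parameter(s): %s",
              paste(unknown, collapse = ", "))
  utils::modifyList(base, params)
}

#' Run the single-cell pipeline end to end
#'
#' Droplet pre-filter, per-cell metrics, sex assignment (undefined excluded),
#' log-normalization, PCA + graph clustering, marker-based cluster annotation,
#' per-cell-type QC gates (applied once a type label exists), one-vs-rest
#' markers, CTRL-vs-SOD1 differential expression per age, pseudobulk PCA, and
#' (when gene sets are supplied) preranked GSEA on the latest-age contrast.
#' The manifest records how many cells each gate removed.
#'
#' @param counts a [count_matrix()] whose metadata carries `sample`,
#'   `condition`, `age`.
#' @param annotation a [gene_annotation()].
#' @param canonical_markers named list type -> marker genes for cluster
#'   annotation.
#' @param gene_sets optional named list of gene sets for GSEA.
#' @param params list of overrides of [default_parameters()].
#' @param gsea_age age label used for the GSEA contrast (default the
#'   lexicographically last age present, i.e. "4M" in the standard design).
#' @return list with `cell_meta` (per-cell table: sex, cluster, cell_type,
#'   qc_keep), `clusters`, `cluster_annotation`, `markers`, `de` (per age),
#'   `pseudobulk`, `pseudobulk_pca`, `gsea` (or NULL), `manifest`.
#' @export
run_sc_pipeline <- function(counts, annotation, canonical_markers,
                            gene_sets = NULL, params = NULL,
                            gsea_age = NULL) {
  p <- merge_params(params)
  stopifnot(inherits(counts, "glia_counts"))
  manifest <- list(n_input = ncol(counts$counts))

  filtered <- filter_droplets(counts, min_umi = p$min_umi)
  manifest$n_after_umi_filter <- ncol(filtered$counts)
  manifest$removed_umi_filter <- manifest$n_input - manifest$n_after_umi_filter

  metrics <- compute_cell_metrics(filtered, annotation)
  sex <- assign_sex(metrics)
  keep_sex <- sex != "undefined"
  manifest$removed_undefined_sex <- sum(!keep_sex)
  dat <- subset_cells(filtered, cells = which(keep_sex))
  dat$cell_meta$assigned_sex <- as.character(sex[keep_sex])
  metrics <- metrics[keep_sex, , drop = FALSE]
  manifest$n_after_sex <- ncol(dat$counts)

  norm <- lognormalize(dat, scale_factor = p$scale_factor)
  ## mitochondrial/ribosomal genes, sex-linked genes and the flagged
  ## confounders stay out of the clustering space (they stratify cells by
  ## state or sex, not by type) but remain in the matrix for DE
  excl <- annotation$gene[annotation$is_mito | annotation$is_ribo |
                            annotation$is_excluded_confounder |
                            (!is.na(annotation$chromosome) &
                               annotation$chromosome %in% c("X", "Y"))]
  emb <- pca_embed(norm, n_pcs = p$n_pcs, n_hvg = p$n_hvg,
                   scale_cap = p$scale_cap, exclude_genes = excl)
  cl <- cluster_cells(emb$embedding, k_neighbors = p$k_neighbors,
                      resolution = p$resolution, seed = p$seed)
  ann_cl <- annotate_clusters(norm, cl$labels, canonical_markers,
                              min_expressing = p$min_expressing)
  type_of_cluster <- setNames(ann_cl$label, ann_cl$cluster)
  cell_type <- type_of_cluster[as.character(cl$labels)]
  dat$cell_meta$cluster <- as.character(cl$labels)
  dat$cell_meta$cell_type <- unname(cell_type)

  ## per-type QC gates where a gate exists for the annotated type
  qc_keep <- rep(TRUE, ncol(dat$counts))
  for (ty in intersect(unique(cell_type), names(p$qc_thresholds))) {
    sel <- which(cell_type == ty)
    qc_keep[sel] <- apply_celltype_qc(metrics[sel, , drop = FALSE], ty,
                                      thresholds = p$qc_thresholds[[ty]])
  }
  qc_keep[cell_type == "ambiguous"] <- FALSE
  manifest$removed_qc_gates <- sum(cell_type != "ambiguous" & !qc_keep)
  manifest$removed_ambiguous_clusters <- sum(cell_type == "ambiguous")
  dat$cell_meta$qc_keep <- qc_keep
  stop_if_not(any(qc_keep),
              "qc_gates: no cell survives the per-type thresholds")
  retained <- subset_cells(dat, cells = which(qc_keep))
  manifest$n_retained <- ncol(retained$counts)

  norm_r <- lognormalize(retained, scale_factor = p$scale_factor)
  clusters_r <- droplevels(cl$labels[qc_keep])
  markers <- if (nlevels(clusters_r) >= 2 && min(table(clusters_r)) >= 3)
    find_markers_all(norm_r, clusters_r, min_pct = p$marker_min_pct,
                     min_log2fc = p$marker_min_log2fc) else NULL

  meta_r <- retained$cell_meta
  de <- list()
  for (age in sort(unique(meta_r$age))) {
    a_cells <- rownames(meta_r)[meta_r$age == age & meta_r$condition == "SOD1"]
    b_cells <- rownames(meta_r)[meta_r$age == age & meta_r$condition == "CTRL"]
    if (length(a_cells) >= 3 && length(b_cells) >= 3)
      de[[age]] <- differential_expression(norm_r, a_cells, b_cells,
                                           alpha = p$de_alpha,
                                           lfc_threshold = p$de_lfc)
  }
  manifest$de_contrasts <- names(de)

  pb_keys <- intersect(c("condition", "age", "assigned_sex"), names(meta_r))
  pb <- pseudobulk(retained, keys = pb_keys)
  pb_pca <- if (ncol(pb$matrix) >= 3) pseudobulk_pca(pb) else NULL

  gsea <- NULL
  if (!is.null(gene_sets) && length(de)) {
    gsea_age <- gsea_age %||% utils::tail(sort(names(de)), 1)
    ranked <- rank_genes(de[[gsea_age]])
    sizes <- vapply(gene_sets, function(s)
      length(intersect(s, names(ranked))), integer(1))
    if (any(sizes >= p$gsea_min_size & sizes <= p$gsea_max_size))
      gsea <- gsea_preranked(ranked, gene_sets, min_size = p$gsea_min_size,
                             max_size = p$gsea_max_size,
                             n_perm = p$gsea_n_perm, seed = p$seed)
    manifest$gsea_sets_tested <- if (is.null(gsea)) 0L else nrow(gsea)
  }

  list(cell_meta = dat$cell_meta, clusters = cl,
       cluster_annotation = ann_cl, markers = markers, de = de,
       pseudobulk = pb, pseudobulk_pca = pb_pca, gsea = gsea,
       params = p, manifest = manifest)
}

#' Run the imaging pipeline over a batch of stacks
#'
#' Applies the quantification matching each job's kind — `"intensity"`
#' (Yen-limited integrated density), `"fiber"` (brightest-substack volume
#' fraction) or `"sholl"` (profile from the thresholded max projection) — and
#' aggregates scalar values per animal.
#'
#' @param jobs data.frame with columns `path` (TIFF written by
#'   [write_stack()]), `kind`, `animal`.
#' @param params overrides of [default_parameters()].
#' @return list with `results` (per job), `per_animal` (mean scalar value per
#'   animal and kind), `manifest`.
#' @export
run_imaging_pipeline <- function(jobs, params = NULL) {
  p <- merge_params(params)
  stop_if_not(is.data.frame(jobs) && nrow(jobs) > 0,
              "no imaging jobs supplied")
  stop_if_not(all(c("path", "kind", "animal") %in% names(jobs)),
              "jobs needs columns path, kind, animal")
  results <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    stack <- read_stack(jobs$path[i])
    results[[i]] <- switch(
      jobs$kind[i],
      intensity = integrated_density_limited(stack),
      fiber = fiber_volume_fraction(stack, n_frames = p$n_brightest_frames),
      sholl = sholl_from_stack(stack, r_start = p$sholl_r_start,
                               r_step = p$sholl_r_step),
      stop(sprintf("unknown job kind '%s'", jobs$kind[i]))
    )
  }
  scalar <- vapply(results, function(r)
    if (inherits(r, "quant_result")) r$value else NA_real_, numeric(1))
  per_animal <- aggregate(scalar ~ animal + kind,
                          data = cbind(jobs, scalar = scalar),
                          FUN = mean, na.action = stats::na.omit)
  list(results = results, per_animal = per_animal,
       manifest = list(n_images = nrow(jobs),
                       kinds = table(jobs$kind)))
}
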