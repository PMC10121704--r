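#' Configuration for the single-cell count simulator
#'
#' Defines the simulated study: a 16-sample design (2 conditions x 4 ages x
#' 2 sexes), three dominant glial types, negative-binomial UMI counts with
#' per-cell lognormal library sizes, marker-gene elevation, Xist/Y sex
#' structure, a 3.9% doublet rate and 1.5% ambient contamination. Every
#' default is the emulated study condition; tests and examples scale down
#' `n_cells_per_sample` and `n_genes`, not the rates.
#'
#' @param n_cells_per_sample cells emitted per sample (the emulated study
#'   ranged from 2,500 to 6,800).
#' @param samples data.frame with columns `sample`, `condition` (CTRL/SOD1),
#'   `age`, `sex` ("male", "female", or "mixed" for pooled-sex droplets).
#'   Default: the full 2 x 4 x 2 design at ages 1M-4M.
#' @param cell_type_proportions named fractions summing to 1.
#' @param n_genes size of the gene universe (>= markers + sex genes).
#' @param marker_table named list: cell type -> named numeric vector of
#'   mean fold-elevations per marker gene. `NULL` builds a default table with
#'   canonical glial markers (Aqp4/Aldh1l1/Gjb6, Cx3cr1/P2ry12/Tmem119,
#'   Plp1/Mbp/Mog) plus synthetic markers, all at fold 8.
#' @param sex_genes list with `xist_gene` and `y_genes`.
#' @param condition_effects list of planted effects, each a list with fields
#'   `genes` (character), `log2fc` (numeric), optional `cell_type` (NULL = all
#'   types) and `ages` (NULL = all ages); applied in SOD1 samples only.
#' @param condition_exclusive_types cell types present only in SOD1 samples
#'   (their proportion is reassigned pro rata in CTRL samples).
#' @param doublet_rate fraction of droplets containing two cells.
#' @param ambient_fraction fraction of each droplet's counts drawn from the
#'   sample-wide mean expression profile.
#' @param mito_fraction_mean mean fraction of counts from mt- genes.
#' @param libsize_lognormal `c(mu, sigma)` of log library size.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param xist_fraction,y_gene_fraction expression of Xist (females) and of
#'   each Y gene (males) as a fraction of the transcriptome.
#' @param effect_gene_fraction baseline expression fraction given to each
#'   planted condition-effect gene, so effects act on moderately expressed
#'   genes rather than on whatever the lognormal draw happened to give.
#' @param seed integer seed; the same config is bit-reproducible.
#' @return a `sim_count_config` list, validated.
#' @export
sim_count_config <- function(n_cells_per_sample = 4000,
                             samples = NULL,
                             cell_type_proportions = c(astrocyte = 0.40,
                                                       microglia = 0.35,
                                                       oligodendrocyte = 0.25),
                             n_genes = 1200,
                             marker_table = NULL,
                             sex_genes = list(xist_gene = "Xist",
                                              y_genes = c("Ddx3y", "Eif2s3y",
                                                          "Uty", "Kdm5d")),
                             condition_effects = list(),
                             condition_exclusive_types = character(),
                             doublet_rate = 0.039,
                             ambient_fraction = 0.015,
                             mito_fraction_mean = 0.03,
                             libsize_lognormal = c(mu = log(5000), sigma = 0.30),
                             nb_dispersion = 0.1,
                             xist_fraction = 0.003,
                             y_gene_fraction = 4e-4,
                             effect_gene_fraction = 5e-4,
                             seed = 1L) {
  if (is.null(samples)) {
    samples <- expand.grid(condition = c("CTRL", "SOD1"),
                           age = c("1M", "2M", "3M", "4M"),
                           sex = c("female", "male"),
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_%s_%s", samples$condition, samples$age,
                              substr(samples$sex, 1, 1))
  }
  stop_if_not(all(c("sample", "condition", "age", "sex") %in% names(samples)),
              "samples needs columns sample, condition, age, sex")
  stop_if_not(abs(sum(cell_type_proportions) - 1) < 1e-8,
              "cell_type_proportions must sum to 1")
  stop_if_not(doublet_rate >= 0 && doublet_rate < 1 &&
                ambient_fraction >= 0 && ambient_fraction < 1,
              "doublet_rate and ambient_fraction must be in [0, 1)")
  stop_if_not(all(condition_exclusive_types %in% names(cell_type_proportions)),
              "condition_exclusive_types must name known cell types")
  if (is.null(marker_table))
    marker_table <- default_marker_table(names(cell_type_proportions))
  stop_if_not(all(names(marker_table) %in% names(cell_type_proportions)),
              "marker_table names must be cell types")
  n_named <- length(unlist(lapply(marker_table, names))) +
    1 + length(sex_genes$y_genes)
  stop_if_not(n_genes >= n_named + 50,
              "n_genes too small for markers + sex genes")
  cfg <- list(n_cells_per_sample = as.integer(n_cells_per_sample),
              samples = samples,
              cell_type_proportions = cell_type_proportions,
              n_genes = as.integer(n_genes), marker_table = marker_table,
              sex_genes = sex_genes, condition_effects = condition_effects,
              condition_exclusive_types = condition_exclusive_types,
              doublet_rate = doublet_rate, ambient_fraction = ambient_fraction,
              mito_fraction_mean = mito_fraction_mean,
              libsize_lognormal = libsize_lognormal,
              nb_dispersion = nb_dispersion,
              xist_fraction = xist_fraction,
              y_gene_fraction = y_gene_fraction,
              effect_gene_fraction = effect_gene_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_count_config"
  cfg
}

default_marker_table <- function(types) {
  canonical <- list(astrocyte = c("Aqp4", "Aldh1l1", "Gjb6"),
                    microglia = c("Cx3cr1", "P2ry12", "Tmem119"),
                    oligodendrocyte = c("Plp1", "Mbp", "Mog"))
  out <- lapply(seq_along(types), function(i) {
    ty <- types[i]
    base <- canonical[[ty]] %||% character()
    extra <- sprintf("%sMk%d", toupper(substr(ty, 1, 3)),
                     seq_len(10 - length(base)))
    setNames(rep(8, 10), c(base, extra))
  })
  names(out) <- types
  out
}

## build the gene universe and per-(type, sex, condition-stratum) expression
## fractions; returns list(genes, annotation-ready chromosome, profile fn)
build_gene_model <- function(cfg) {
  markers <- lapply(cfg$marker_table, names)
  marker_genes <- unique(unlist(markers))
  n_mito <- 13L
  n_ribo <- 20L
  mito_genes <- sprintf("mt-Nd%d", seq_len(n_mito))
  ribo_genes <- c(sprintf("Rps%d", 1:10), sprintf("Rpl%d", 1:10))
  sexg <- c(cfg$sex_genes$xist_gene, cfg$sex_genes$y_genes)
  effect_genes <- unique(unlist(lapply(cfg$condition_effects, `[[`, "genes")))
  named <- unique(c(marker_genes, mito_genes, ribo_genes, sexg, effect_genes))
  n_fill <- cfg$n_genes - length(named)
  stop_if_not(n_fill >= 0, "n_genes smaller than the named gene set")
  fill <- setdiff(sprintf("Gene%04d", seq_len(cfg$n_genes + length(named))),
                  named)[seq_len(n_fill)]
  genes <- c(named, fill)
  chrom <- rep(NA_character_, length(genes))
  chrom[genes %in% cfg$sex_genes$y_genes] <- "Y"
  chrom[genes == cfg$sex_genes$xist_gene] <- "X"
  chrom[genes %in% mito_genes] <- "MT"

  ## baseline expression fractions (autosomal machinery)
  base <- rlnorm(length(genes), meanlog = 0, sdlog = 1.5)
  names(base) <- genes
  base[sexg] <- 0
  ## fix planted-effect genes at a moderate expression level
  if (length(effect_genes))
    base[effect_genes] <- cfg$effect_gene_fraction * sum(base)
  ## floor marker-gene base expression so fold-elevation yields the near-
  ## ubiquitous detection the annotation rule expects in the marker's type
  base[marker_genes] <- pmax(base[marker_genes],
                             cfg$effect_gene_fraction * sum(base))
  ## mito block carries mito_fraction_mean of the transcriptome
  base[mito_genes] <- base[mito_genes] /
    sum(base[mito_genes]) * cfg$mito_fraction_mean /
    (1 - cfg$mito_fraction_mean) * sum(base[setdiff(genes, mito_genes)])

  types <- names(cfg$cell_type_proportions)
  all_markers <- unlist(lapply(cfg$marker_table, names))
  type_profiles <- lapply(types, function(ty) {
    p <- base * 2^rnorm(length(base), 0, 0.25)
    mk <- cfg$marker_table[[ty]]
    ## markers: elevated in their own type, suppressed elsewhere so the
    ## expressing-fraction annotation rule discriminates between types
    p[setdiff(all_markers, names(mk))] <-
      p[setdiff(all_markers, names(mk))] * 0.02
    if (length(mk)) p[names(mk)] <- p[names(mk)] * mk
    p[sexg] <- 0
    p
  })
  names(type_profiles) <- types
  list(genes = genes, chromosome = chrom, type_profiles = type_profiles,
       mito_genes = mito_genes)
}

## expression fractions for one cell given type, sex and sample stratum
cell_profile <- function(model, cfg, type, sex, condition, age) {
  p <- model$type_profiles[[type]]
  if (condition == "SOD1") {
    for (eff in cfg$condition_effects) {
      if (!is.null(eff$cell_type) && !(type %in% eff$cell_type)) next
      if (!is.null(eff$ages) && !(age %in% eff$ages)) next
      p[eff$genes] <- p[eff$genes] * 2^eff$log2fc
    }
  }
  tot <- sum(p)
  if (sex == "female") p[cfg$sex_genes$xist_gene] <- cfg$xist_fraction * tot
  if (sex == "male") p[cfg$sex_genes$y_genes] <- cfg$y_gene_fraction * tot
  p / sum(p)
}

#' Simulate a droplet scRNA-seq count matrix with planted ground truth
#'
#' UMI counts are negative-binomial with gene fractions set by cell type
#' (markers elevated), sex (Xist only in female singlets, Y genes only in male
#' singlets) and planted condition effects. Doublets sum two independently
#' drawn singlet profiles; ambient contamination adds Poisson counts from the
#' sample-mean profile at `ambient_fraction` of the droplet's library size.
#'
#' @param config a [sim_count_config()].
#' @param keep_parents if TRUE, attach the two parent singlet count matrices
#'   of each doublet (attribute `"parents"`) for conservation checks.
#' @return list with `counts` (a [count_matrix()] with sample/condition/age
#'   metadata), `truth` (data.frame: barcode, sample, condition, age, sex,
#'   cell_type, is_doublet, subpop) and `annotation` (a [gene_annotation()]).
#'   The planted effect gene lists are kept as `attr(truth, "de_genes")`.
#' @examples
#' cfg <- sim_count_config(n_cells_per_sample = 50, n_genes = 300,
#'                         samples = data.frame(sample = "s1", condition = "CTRL",
#'                                              age = "4M", sex = "mixed"))
#' sim <- simulate_counts(cfg)
#' table(sim$truth$cell_type)
#' @export
simulate_counts <- function(config, keep_parents = FALSE) {
  stopifnot(inherits(config, "sim_count_config"))
  cfg <- config
  with_seed(cfg$seed, {
    model <- build_gene_model(cfg)
    genes <- model$genes
    size <- 1 / cfg$nb_dispersion
    types <- names(cfg$cell_type_proportions)
    blocks <- list(); truths <- list(); parents <- list()
    for (si in seq_len(nrow(cfg$samples))) {
      srow <- cfg$samples[si, ]
      n <- cfg$n_cells_per_sample
      props <- cfg$cell_type_proportions
      if (srow$condition == "CTRL" && length(cfg$condition_exclusive_types)) {
        props[cfg$condition_exclusive_types] <- 0
        props <- props / sum(props)
      }
      cell_type <- sample(types, n, replace = TRUE, prob = props)
      cell_sex <- if (srow$sex == "mixed")
        sample(c("female", "male"), n, replace = TRUE) else rep(srow$sex, n)
      is_doublet <- runif(n) < cfg$doublet_rate
      libsize <- rlnorm(n, cfg$libsize_lognormal[1], cfg$libsize_lognormal[2])

      ## per-(type, sex) profile cache for this sample stratum
      prof_key <- paste(cell_type, cell_sex)
      profs <- lapply(unique(prof_key), function(k) {
        ts <- strsplit(k, " ", fixed = TRUE)[[1]]
        cell_profile(model, cfg, ts[1], ts[2], srow$condition, srow$age)
      })
      names(profs) <- unique(prof_key)
      prof_mat <- vapply(prof_key, function(k) profs[[k]], numeric(length(genes)))

      a <- cfg$ambient_fraction
      mu <- prof_mat * rep((1 - a) * libsize, each = length(genes))
      counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                       nrow = length(genes))

      partner_type <- rep(NA_character_, n)
      partner_sex <- rep(NA_character_, n)
      if (any(is_doublet)) {
        idx <- which(is_doublet)
        partner_type[idx] <- sample(types, length(idx), replace = TRUE,
                                    prob = props)
        partner_sex[idx] <- if (srow$sex == "mixed")
          sample(c("female", "male"), length(idx), replace = TRUE)
          else rep(srow$sex, length(idx))
        lib2 <- rlnorm(length(idx), cfg$libsize_lognormal[1],
                       cfg$libsize_lognormal[2])
        for (j in seq_along(idx)) {
          k <- paste(partner_type[idx[j]], partner_sex[idx[j]])
          if (is.null(profs[[k]]))
            profs[[k]] <- cell_profile(model, cfg, partner_type[idx[j]],
                                       partner_sex[idx[j]],
                                       srow$condition, srow$age)
          mu2 <- profs[[k]] * (1 - a) * lib2[j]
          second <- rnbinom(length(genes), mu = mu2, size = size)
          if (keep_parents)
            parents[[paste0(srow$sample, "_cell", idx[j])]] <-
              cbind(first = counts[, idx[j]], second = second)
          counts[, idx[j]] <- counts[, idx[j]] + second
          libsize[idx[j]] <- libsize[idx[j]] + lib2[j]
        }
      }

      if (a > 0) {
        ambient_prof <- rowMeans(prof_mat)
        amb_mu <- ambient_prof %o% (a * libsize)
        counts <- counts + matrix(rpois(length(amb_mu), amb_mu),
                                  nrow = length(genes))
      }

      rownames(counts) <- genes
      colnames(counts) <- paste0(srow$sample, "_cell", seq_len(n))
      blocks[[si]] <- as(counts, "CsparseMatrix")
      truths[[si]] <- data.frame(
        barcode = colnames(counts), sample = srow$sample,
        condition = srow$condition, age = srow$age, sex = cell_sex,
        cell_type = ifelse(is_doublet,
                           paste(cell_type, partner_type, sep = "+"),
                           cell_type),
        is_doublet = is_doublet,
        subpop = cell_type,
        stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, blocks)
    truth <- do.call(rbind, truths)
    rownames(truth) <- truth$barcode
    attr(truth, "de_genes") <- lapply(cfg$condition_effects, `[[`, "genes")
    meta <- truth[, c("sample", "condition", "age"), drop = FALSE]
    out <- list(counts = count_matrix(counts, meta), truth = truth,
                annotation = gene_annotation(genes,
                                             chromosome = model$chromosome))
    if (keep_parents) attr(out$truth, "parents") <- parents
    out
  })
}
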