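# Classifier training and genotype prediction. The single model is one
# RBF-kernel SVM per variant type trained on 1 replicate per variant per
# zygosity; the variant model is a per-variant random forest trained on 100
# replicates per zygosity; the hybrid model routes small variants to the
# variant model and the rest to the single model.

#' Classifier configuration
#'
#' @param C_grid,gamma_grid SVM hyperparameter grids for the optional
#'   5-fold-CV grid search; `"scale"` means `1 / n_features` on standardized
#'   data.
#' @param cv_folds Cross-validation folds for the grid search.
#' @param grid_search Whether to run the hyperparameter sweep (off by
#'   default; default parameters are typically as accurate and much faster).
#' @param rf_trees Trees in the per-variant random forest.
#' @param hybrid_threshold Size (bp) below which the hybrid model builds a
#'   per-variant classifier.
#' @param replicates_variant,replicates_single Simulated replicates per
#'   zygosity for the variant and single models.
#' @param outlier_sd Per-feature standard-deviation cutoff for excluding
#'   training observations in the variant model.
#' @return A list of configuration values.
#' @export
classifier_config <- function(C_grid = c(1, 10, 100, 500, 1000, 5000, 10000),
                              gamma_grid = c("scale", 0.001, 0.0055, 0.01,
                                             0.055, 0.1, 0.55),
                              cv_folds = 5L, grid_search = FALSE,
                              rf_trees = 100L, hybrid_threshold = 1000L,
                              replicates_variant = 100L,
                              replicates_single = 1L, outlier_sd = 5) {
  list(C_grid = C_grid, gamma_grid = gamma_grid, cv_folds = cv_folds,
       grid_search = grid_search, rf_trees = as.integer(rf_trees),
       hybrid_threshold = as.integer(hybrid_threshold),
       replicates_variant = as.integer(replicates_variant),
       replicates_single = as.integer(replicates_single),
       outlier_sd = outlier_sd)
}

# Feature matrix from a feature tibble; NAs (zero-denominator depth
# fold-changes) retained for the scaler to handle.
feature_matrix <- function(rows) {
  as.matrix(rows[, feature_names()])
}

# Standardization learned from training rows: per-feature mean/SD computed
# over non-NA values; zero or missing SD scales by 1. NAs are imputed to the
# training mean (z-score 0).
fit_scaler <- function(x) {
  mu <- apply(x, 2, function(c) mean(c[is.finite(c)]))
  mu[!is.finite(mu)] <- 0
  s <- apply(x, 2, function(c) sd(c[is.finite(c)]))
  s[!is.finite(s) | s == 0] <- 1
  list(mean = mu, sd = s)
}

apply_scaler <- function(x, scaler) {
  z <- sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
  z[!is.finite(z)] <- 0
  z
}

#' Train the single (per-sample, per-type) SVM classifier
#'
#' Features are centered and scaled to unit variance (the same scaling is
#' applied at prediction); the classifier is an RBF-kernel SVM with class
#' probabilities. The hyperparameter sweep over `C_grid` x `gamma_grid` with
#' k-fold cross-validation runs only when `grid_search` is enabled. Training
#' rows from variants outside `region_mask` are excluded when a mask is
#' given.
#'
#' @param rows Labeled feature tibble (columns `variant_id`, `label`, and
#'   [feature_names()]), all three zygosity labels present.
#' @param cfg [classifier_config()].
#' @param seed Integer seed (probability calibration is stochastic).
#' @param region_mask Optional BED-like tibble (`contig`, `start`, `end`;
#'   0-based half-open) restricting training variants.
#' @param variants `sv_tbl` used to resolve variant positions for the mask.
#' @return An object of class `svgt_single`.
#' @export
train_single <- function(rows, cfg = classifier_config(), seed = 1,
                         region_mask = NULL, variants = NULL) {
  if (!is.null(region_mask)) {
    if (is.null(variants)) stop("variants required when region_mask is given")
    keep_ids <- variants$variant_id[mask_overlap(variants, region_mask)]
    rows <- rows[rows$variant_id %in% keep_ids, ]
  }
  if (!all(zygosity_levels() %in% rows$label)) {
    stop("all three zygosity classes must be present in the training data")
  }
  x <- feature_matrix(rows)
  scaler <- fit_scaler(x)
  z <- apply_scaler(x, scaler)
  y <- factor(rows$label, levels = zygosity_levels())
  cost <- 1; gamma <- 1 / ncol(z)
  if (isTRUE(cfg$grid_search)) {
    best <- -Inf
    for (C in cfg$C_grid) {
      for (g in cfg$gamma_grid) {
        gv <- if (identical(g, "scale")) 1 / ncol(z) else as.numeric(g)
        set.seed(derive_seed(seed, round(C), round(gv * 1e6)))
        fit <- e1071::svm(z, y, kernel = "radial", cost = C, gamma = gv,
                          cross = cfg$cv_folds, scale = FALSE)
        if (fit$tot.accuracy > best) {
          best <- fit$tot.accuracy; cost <- C; gamma <- gv
        }
      }
    }
  }
  set.seed(seed)
  fit <- e1071::svm(z, y, kernel = "radial", cost = cost, gamma = gamma,
                    probability = TRUE, scale = FALSE)
  structure(list(fit = fit, scaler = scaler, cost = cost, gamma = gamma,
                 n_rows = nrow(rows), features = feature_names()),
            class = "svgt_single")
}

# TRUE for variants whose padding base falls inside any mask interval.
mask_overlap <- function(variants, mask) {
  vapply(seq_len(nrow(variants)), function(i) {
    any(mask$contig == variants$contig[i] &
          mask$start <= variants$pos[i] - 1L &
          mask$end > variants$pos[i] - 1L)
  }, logical(1))
}

#' Train a per-variant random-forest classifier
#'
#' Observations with any feature more than `outlier_sd` standard deviations
#' from its (class-agnostic) mean are excluded before fitting; if that
#' removes an entire class the filter is abandoned with a warning. The forest
#' uses `rf_trees` trees of unrestricted depth and is deterministic for a
#' fixed seed.
#'
#' @inheritParams train_single
#' @return An object of class `svgt_variant`.
#' @export
train_variant <- function(rows, cfg = classifier_config(), seed = 1) {
  if (!all(zygosity_levels() %in% rows$label)) {
    stop("all three zygosity classes must be present in the training data")
  }
  x <- feature_matrix(rows)
  scaler <- fit_scaler(x)
  z <- apply_scaler(x, scaler)
  keep <- apply(abs(z) <= cfg$outlier_sd, 1, all)
  if (!all(zygosity_levels() %in% rows$label[keep])) {
    warning("outlier filter removed an entire class; using unfiltered rows")
    keep <- rep(TRUE, nrow(rows))
  }
  xk <- x[keep, , drop = FALSE]
  # impute NA depth features to the training mean before fitting
  for (j in seq_len(ncol(xk))) xk[!is.finite(xk[, j]), j] <- scaler$mean[j]
  y <- factor(rows$label[keep], levels = zygosity_levels())
  set.seed(seed)
  fit <- randomForest::randomForest(xk, y, ntree = cfg$rf_trees)
  structure(list(fit = fit, scaler = scaler, n_rows = sum(keep),
                 n_excluded = sum(!keep), features = feature_names()),
            class = "svgt_variant")
}

#' Predict genotypes from feature vectors
#'
#' Returns the class probabilities, the argmax genotype (ties broken in the
#' fixed order hom-ref < het < hom-alt), and the Phred-scaled genotype
#' quality `min(99, floor(-10 log10(1 - max(p))))`.
#'
#' @param model `svgt_single` or `svgt_variant`.
#' @param rows Feature tibble (unlabeled).
#' @return Tibble with `variant_id`, `gt`, `p_hom_ref`, `p_het`,
#'   `p_hom_alt`, `gq`.
#' @export
predict_genotype <- function(model, rows) {
  x <- feature_matrix(rows)
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- model$scaler$mean[j]
  probs <- if (inherits(model, "svgt_single")) {
    z <- apply_scaler(x, model$scaler)
    pr <- predict(model$fit, z, probability = TRUE)
    attr(pr, "probabilities")[, zygosity_levels(), drop = FALSE]
  } else {
    predict(model$fit, x, type = "prob")[, zygosity_levels(), drop = FALSE]
  }
  probs <- matrix(probs, ncol = 3,
                  dimnames = list(NULL, zygosity_levels()))
  # argmax with fixed tie order HOM_REF < HET < HOM_ALT
  gt_idx <- apply(probs, 1, which.max)
  tibble(
    variant_id = rows$variant_id,
    gt = zygosity_to_gt(zygosity_levels()[gt_idx]),
    p_hom_ref = probs[, "HOM_REF"],
    p_het = probs[, "HET"],
    p_hom_alt = probs[, "HOM_ALT"],
    gq = phred_gq(probs)
  )
}

#' Simulation-trained genotyping of a variant set
#'
#' The full pipeline for a set of putative SVs against one sample: for each
#' variant, simulate per-zygosity training replicates matched to the sample
#' profile, harvest homozygous-reference training features from the actual
#' alignments at size-matched random locations, extract the identical
#' feature set from the actual alignments, train the configured classifier,
#' and predict the genotype with a quality. Fully deterministic for a fixed
#' seed.
#'
#' @param variants `sv_tbl` of putative SVs.
#' @param alignments Actual alignment tibble (whole sample).
#' @param genome Genome.
#' @param p `sample_profile` (see [estimate_profile()] / [load_profile()]).
#' @param mode `"auto"` (hybrid for deletions, single for insertions),
#'   `"single"`, `"variant"`, or `"hybrid"`.
#' @param cfg [classifier_config()].
#' @param seed Integer seed.
#' @param config [realign_config()].
#' @param contig_partition Contigs eligible for null-variant sampling
#'   (default: all).
#' @param region_mask Optional BED-like tibble restricting single-model
#'   training variants.
#' @return Tibble of calls: `variant_id`, `gt`, class probabilities, `gq`,
#'   `mode_used`.
#' @export
genotype_svs <- function(variants, alignments, genome, p,
                         mode = c("auto", "single", "variant", "hybrid"),
                         cfg = classifier_config(), seed = 1,
                         config = realign_config(),
                         contig_partition = NULL, region_mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(variants) > 0)
  flank <- compute_flank(p)
  route <- route_mode(variants$svtype, variants$svlen, mode, cfg)

  calls <- vector("list", nrow(variants))
  single_rows <- list()      # per-svtype training rows for the single model
  single_actual <- list()    # actual feature rows awaiting a single model
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    res <- tryCatch({
      n_rep <- if (route[i] == "variant") cfg$replicates_variant
               else cfg$replicates_single
      tr <- training_features(v, alignments, genome, p, n_rep, flank, seed,
                              config, contig_partition, exclude = variants)
      ctx <- allele_contexts(v, genome, flank)
      act <- extract_features(alignments, v, ctx, p, genome, config)
      list(train = tr, actual = act)
    }, error = function(e) {
      warning("variant ", v$variant_id, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      calls[[i]] <- tibble(variant_id = v$variant_id, gt = "./.",
                           p_hom_ref = NA_real_, p_het = NA_real_,
                           p_hom_alt = NA_real_, gq = NA_integer_,
                           mode_used = route[i])
      next
    }
    if (route[i] == "variant") {
      mdl <- train_variant(res$train, cfg,
                           seed = derive_seed(seed, 7, i))
      calls[[i]] <- predict_genotype(mdl, res$actual) %>%
        mutate(mode_used = "variant")
    } else {
      single_rows[[v$svtype]] <- bind_rows(single_rows[[v$svtype]], res$train)
      single_actual[[length(single_actual) + 1]] <-
        res$actual %>% mutate(.row = i, svtype = v$svtype)
    }
  }
  if (length(single_actual) > 0) {
    act <- bind_rows(single_actual)
    for (st in unique(act$svtype)) {
      mdl <- train_single(single_rows[[st]], cfg,
                          seed = derive_seed(seed, 11, match(st, c("DEL", "INS"))),
                          region_mask = region_mask, variants = variants)
      sub <- act[act$svtype == st, ]
      pred <- predict_genotype(mdl, sub) %>% mutate(mode_used = "single")
      for (k in seq_len(nrow(sub))) calls[[sub$.row[k]]] <- pred[k, ]
    }
  }
  bind_rows(calls)
}

#' Resolve which classifier each variant is routed to
#'
#' `"auto"` uses the hybrid model for deletions and the single model for
#' insertions; `"hybrid"` routes variants smaller than the hybrid threshold
#' to the per-variant classifier and the rest to the single model.
#'
#' @param svtype,svlen Vectors describing the variants.
#' @param mode Requested mode.
#' @param cfg [classifier_config()].
#' @return Character vector of `"single"` / `"variant"` per variant.
#' @export
route_mode <- function(svtype, svlen, mode = c("auto", "single", "variant",
                                               "hybrid"),
                       cfg = classifier_config()) {
  mode <- match.arg(mode)
  m <- if (mode == "auto") ifelse(svtype == "DEL", "hybrid", "single")
       else rep(mode, length(svtype))
  ifelse(m == "hybrid",
         ifelse(abs(svlen) < cfg$hybrid_threshold, "variant", "single"),
         m)
}

# Realignment-context flank: wide enough that both mates of any pair
# recruited within the 99th-insert-percentile distance of a breakpoint lie
# wholly inside the context, keeping the exact-substring alignment fast path
# effective.
compute_flank <- function(p) {
  as.integer(insert_q99(p) + p$insert_mean + 2L * p$read_length)
}

# Simulation flank: the depth-feature flanks (depth_flank beyond the event)
# must lie in the interior coverage plateau, which starts about one large
# insert inside the simulated window; realignment recruits reads only
# within the 99th insert percentile of a breakpoint, well inside that.
compute_sim_flank <- function(p, config) {
  as.integer(config$depth_flank + insert_q99(p) + 2L * p$read_length)
}

#' Labeled training features for one variant
#'
#' HET and HOM_ALT rows come from simulated, realigned replicates; HOM_REF
#' rows are extracted from the actual alignments at size-matched null
#' locations (set `hom_ref_sim = TRUE` to simulate them instead).
#'
#' @inheritParams genotype_svs
#' @param v One-row `sv_tbl`.
#' @param n_per_zygosity Rows per zygosity.
#' @param flank Context flank (bp).
#' @param hom_ref_sim Simulate HOM_REF rows instead of null sampling.
#' @param exclude `sv_tbl` of regions null windows must avoid (default: the
#'   variant itself; the genotyping pipeline passes the whole call set).
#' @return Labeled feature tibble with `3 * n_per_zygosity` rows.
#' @export
training_features <- function(v, alignments, genome, p, n_per_zygosity,
                              flank, seed, config = realign_config(),
                              contig_partition = NULL, hom_ref_sim = FALSE,
                              exclude = v) {
  vhash <- sum(utf8ToInt(v$variant_id))
  ctx <- allele_contexts(v, genome, flank)
  sflank <- compute_sim_flank(p, config)
  sim_rows <- purrr::map_dfr(c("HET", "HOM_ALT"), function(z) {
    zi <- match(z, zygosity_levels())
    purrr::map_dfr(seq_len(n_per_zygosity), function(k) {
      reads <- simulate_replicate(v, genome, z, p, sflank,
                                  seed = derive_seed(seed, vhash, zi, k))
      extract_features(reads, v, ctx, p, genome, config, label = z)
    })
  })
  ref_rows <- if (hom_ref_sim) {
    purrr::map_dfr(seq_len(n_per_zygosity), function(k) {
      reads <- simulate_replicate(v, genome, "HOM_REF", p, sflank,
                                  seed = derive_seed(seed, vhash, 1, k))
      extract_features(reads, v, ctx, p, genome, config, label = "HOM_REF")
    })
  } else {
    purrr::map_dfr(seq_len(n_per_zygosity), function(k) {
      set.seed(derive_seed(seed, vhash, 1, k))
      nv <- sample_null_variant(v, genome, contig_partition, flank = flank,
                                exclude = exclude)
      nctx <- allele_contexts(nv, genome, flank)
      extract_features(alignments, nv, nctx, p, genome, config,
                       label = "HOM_REF") %>%
        mutate(variant_id = v$variant_id)
    })
  }
  bind_rows(ref_rows, sim_rows)
}

#' Genotype a VCF of putative SVs against a BAM
#'
#' File-level wrapper over [genotype_svs()]: parses the VCF, loads or
#' estimates the sample profile, genotypes, and writes a genotyped copy of
#' the call set. Output is byte-identical across runs with the same inputs
#' and seed.
#'
#' @param vcf Input VCF path.
#' @param bam BAM path (or alignment tibble).
#' @param genome FASTA path (or genome object).
#' @param out Output VCF path.
#' @param stats_file Optional key=value metrics file; when absent the
#'   profile is estimated from the alignments.
#' @inheritParams genotype_svs
#' @param ... Passed to [genotype_svs()].
#' @return The calls tibble, invisibly; writes `out`.
#' @export
genotype_vcf <- function(vcf, bam, genome, out,
                         mode = c("auto", "single", "variant", "hybrid"),
                         cfg = classifier_config(), seed = 1,
                         stats_file = NULL, ...) {
  mode <- match.arg(mode)
  if (is.character(genome)) genome <- read_genome(genome)
  variants <- parse_sv_vcf(vcf)
  alignments <- as_read_tbl(bam)
  p <- if (!is.null(stats_file)) load_profile(stats_file)
       else estimate_profile(alignments, genome)
  calls <- genotype_svs(variants, alignments, genome, p, mode = mode,
                        cfg = cfg, seed = seed, ...)
  write_genotyped_vcf(variants, calls, out)
  invisible(calls)
}

#' @export
print.svgt_single <- function(x, ...) {
  cat("<svgt_single> RBF SVM, cost=", x$cost, ", gamma=", signif(x$gamma, 4),
      ", trained on ", x$n_rows, " rows\n", sep = "")
  invisible(x)
}

#' @export
print.svgt_variant <- function(x, ...) {
  cat("<svgt_variant> random forest, ", x$fit$ntree, " trees, trained on ",
      x$n_rows, " rows (", x$n_excluded, " outliers excluded)\n", sep = "")
  invisible(x)
}

#' Tidy classifier summaries
#'
#' `tidy()` returns per-feature scaling (and RF importance); `glance()`
#' returns one-row fit summaries.
#'
#' @param x A fitted `svgt_single` or `svgt_variant`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.svgt_single <- function(x, ...) {
  tibble(feature = x$features, mean = unname(x$scaler$mean),
         sd = unname(x$scaler$sd))
}

#' @rdname tidy.svgt_single
#' @export
tidy.svgt_variant <- function(x, ...) {
  imp <- randomForest::importance(x$fit)
  tibble(feature = rownames(imp), importance = unname(imp[, 1]),
         mean = unname(x$scaler$mean[rownames(imp)]),
         sd = unname(x$scaler$sd[rownames(imp)]))
}

#' @rdname tidy.svgt_single
#' @export
glance.svgt_single <- function(x, ...) {
  tibble(model = "single", classifier = "svm_rbf", cost = x$cost,
         gamma = x$gamma, n_rows = x$n_rows,
         n_support = sum(x$fit$nSV))
}

#' @rdname tidy.svgt_single
#' @export
glance.svgt_variant <- function(x, ...) {
  tibble(model = "variant", classifier = "random_forest",
         n_trees = x$fit$ntree, n_rows = x$n_rows,
         n_excluded = x$n_excluded,
         oob_error = unname(x$fit$err.rate[x$fit$ntree, "OOB"]))
}
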