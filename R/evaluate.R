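# Call-set evaluation: variant matching, genotype concordance,
# Mendelian-error analysis, and breakpoint-offset stratification.

#' Match a call set to a truth set
#'
#' Candidate pairs share a contig and SV type, lie within `window` bp, and
#' satisfy size similarity (`min(|svlen|) / max(|svlen|) >= size_sim`) and
#' sequence similarity (normalized edit similarity of the alt-defining
#' sequences: the deleted reference bases for deletions, the inserted bases
#' for insertions). Pairs are assigned one-to-one greedily in order of
#' descending combined similarity.
#'
#' @param calls,truth `sv_tbl` tibbles (a `gt` column is carried through if
#'   present).
#' @param window Maximum breakpoint distance (bp).
#' @param size_sim,seq_sim Similarity thresholds in `[0, 1]`.
#' @return A `match_result`: list with `pairs` (tibble with call/truth ids,
#'   genotypes, offsets, similarities), `unmatched_calls`, `unmatched_truth`.
#' @export
match_variants <- function(calls, truth, window = 2000, size_sim = 0.70,
                           seq_sim = 0.70) {
  cand <- tidyr::crossing(ci = seq_len(nrow(calls)), ti = seq_len(nrow(truth)))
  if (nrow(cand) > 0) {
    cand <- cand %>%
      filter(calls$contig[.data$ci] == truth$contig[.data$ti],
             calls$svtype[.data$ci] == truth$svtype[.data$ti],
             abs(calls$pos[.data$ci] - truth$pos[.data$ti]) <= window) %>%
      mutate(
        ssim = pmin(abs(calls$svlen[.data$ci]), abs(truth$svlen[.data$ti])) /
          pmax(abs(calls$svlen[.data$ci]), abs(truth$svlen[.data$ti])),
        qsim = seq_similarity(calls[.data$ci, ], truth[.data$ti, ])
      ) %>%
      filter(.data$ssim >= size_sim, .data$qsim >= seq_sim) %>%
      arrange(dplyr::desc(.data$ssim + .data$qsim), .data$ci, .data$ti)
  }
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    ci <- cand$ci[r]; ti <- cand$ti[r]
    if (!used_c[ci] && !used_t[ti]) {
      used_c[ci] <- TRUE; used_t[ti] <- TRUE
      keep <- c(keep, r)
    }
  }
  cand <- cand[keep, ]
  pairs <- tibble(
    call_id = calls$variant_id[cand$ci],
    truth_id = truth$variant_id[cand$ti],
    call_gt = if ("gt" %in% names(calls)) calls$gt[cand$ci] else NA_character_,
    truth_gt = if ("gt" %in% names(truth)) truth$gt[cand$ti] else NA_character_,
    start_offset = abs(calls$pos[cand$ci] - truth$pos[cand$ti]),
    end_offset = abs(calls$end[cand$ci] - truth$end[cand$ti]),
    size_similarity = cand$ssim,
    seq_similarity = cand$qsim
  ) %>%
    mutate(max_offset = pmax(.data$start_offset, .data$end_offset))
  structure(list(pairs = pairs,
                 unmatched_calls = calls[!used_c, ],
                 unmatched_truth = truth[!used_t, ]),
            class = "match_result")
}

# Normalized edit similarity of alt-defining sequences (1 - edit distance /
# max length); both deletions compare deleted reference bases, insertions
# compare inserted bases.
seq_similarity <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sa <- alt_defining_seq(a[i, ]); sb <- alt_defining_seq(b[i, ])
    ml <- max(nchar(sa), nchar(sb))
    if (ml == 0) return(1)
    1 - utils::adist(sa, sb)[1, 1] / ml
  }, numeric(1))
}

alt_defining_seq <- function(v) {
  if (v$svtype == "DEL") substr(v$ref, 2, nchar(v$ref))
  else substr(v$alt, 2, nchar(v$alt))
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " matched pair(s), ",
      nrow(x$unmatched_calls), " unmatched call(s), ",
      nrow(x$unmatched_truth), " unmatched truth variant(s)\n", sep = "")
  invisible(x)
}

#' Genotype concordance of matched pairs
#'
#' Computes the truth-by-called genotype confusion table, the exact genotype
#' concordance, and the non-reference concordance (heterozygous and
#' homozygous alternate collapsed to one class). Precision, recall, and F1
#' are computed for the hom-ref vs non-ref binarization; unmatched truth
#' variants with non-reference genotypes count against recall, and
#' non-reference unmatched calls count against precision.
#'
#' @param m A `match_result` whose pairs carry genotypes (or supply
#'   `call_gts`/`truth_gts` named by variant id).
#' @param call_gts,truth_gts Optional named genotype vectors overriding the
#'   genotypes stored in the match.
#' @param exclude_nocall Drop pairs whose call genotype is `./.` from the
#'   concordance denominators (no-calls are always reported in the table).
#' @return A `concordance_report`: list with `confusion` (4x4 table),
#'   `genotype_concordance`, `nonref_concordance`, `precision`, `recall`,
#'   `f1`, `n_pairs`.
#' @export
concordance <- function(m, call_gts = NULL, truth_gts = NULL,
                        exclude_nocall = FALSE) {
  pairs <- m$pairs
  cg <- if (!is.null(call_gts)) unname(call_gts[pairs$call_id]) else pairs$call_gt
  tg <- if (!is.null(truth_gts)) unname(truth_gts[pairs$truth_id]) else pairs$truth_gt
  cg[is.na(cg) | !cg %in% gt_levels()] <- "./."
  tg[is.na(tg) | !tg %in% gt_levels()] <- "./."
  confusion <- table(factor(tg, levels = gt_levels()),
                     factor(cg, levels = gt_levels()),
                     dnn = c("truth", "called"))
  use <- if (exclude_nocall) cg != "./." else rep(TRUE, length(cg))
  n <- sum(use)
  gc_frac <- if (n == 0) NA_real_ else mean(cg[use] == tg[use])
  collapse <- function(g) ifelse(g %in% c("0/1", "1/1"), "NONREF", g)
  nr_frac <- if (n == 0) NA_real_ else mean(collapse(cg[use]) == collapse(tg[use]))
  # hom-ref vs non-ref binarization
  call_nr <- cg %in% c("0/1", "1/1")
  truth_nr <- tg %in% c("0/1", "1/1")
  um_truth_nr <- if ("gt" %in% names(m$unmatched_truth)) {
    sum(m$unmatched_truth$gt %in% c("0/1", "1/1"), na.rm = TRUE)
  } else 0
  um_call_nr <- if ("gt" %in% names(m$unmatched_calls)) {
    sum(m$unmatched_calls$gt %in% c("0/1", "1/1"), na.rm = TRUE)
  } else 0
  tp <- sum(call_nr & truth_nr)
  fp <- sum(call_nr & !truth_nr) + um_call_nr
  fn <- sum(!call_nr & truth_nr) + um_truth_nr
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(confusion = confusion, genotype_concordance = gc_frac,
                 nonref_concordance = nr_frac, precision = precision,
                 recall = recall, f1 = f1, n_pairs = n),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> n=", x$n_pairs,
      " genotype=", round(x$genotype_concordance, 4),
      " nonref=", round(x$nonref_concordance, 4),
      " F1=", round(x$f1, 4), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @rdname concordance
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, genotype_concordance = x$genotype_concordance,
         nonref_concordance = x$nonref_concordance, precision = x$precision,
         recall = x$recall, f1 = x$f1)
}

#' @rdname concordance
#' @export
tidy.concordance_report <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion, stringsAsFactors = FALSE)) %>%
    rename(n = "Freq")
}

#' Mendelian-error analysis for a trio
#'
#' A site is a Mendelian error iff no pair of transmitted parental alleles
#' can produce the child genotype. Errors are categorized as heterozygous de
#' novo (child 0/1, parents both 0/0), homozygous de novo (child 1/1,
#' parents both 0/0), or other. Sites with any missing genotype are excluded
#' from the denominator, as are sites whose minimum trio GQ falls below
#' `min_gq` when GQs are provided.
#'
#' @param trio Tibble with columns `child`, `mother`, `father` (genotype
#'   strings) and optionally `child_gq`, `mother_gq`, `father_gq`.
#' @param min_gq Optional minimum trio GQ filter.
#' @return A `trio_report`: list with `mer`, `n_errors`, `n_sites`,
#'   `het_denovo`, `hom_denovo`, `other`, and the per-site tibble `sites`.
#' @export
mendelian <- function(trio, min_gq = NULL) {
  trio <- as_tibble(trio)
  complete <- !is.na(trio$child) & !is.na(trio$mother) & !is.na(trio$father) &
    trio$child != "./." & trio$mother != "./." & trio$father != "./."
  if (!is.null(min_gq) && all(c("child_gq", "mother_gq", "father_gq") %in%
                              names(trio))) {
    mgq <- pmin(trio$child_gq, trio$mother_gq, trio$father_gq)
    complete <- complete & !is.na(mgq) & mgq >= min_gq
  }
  sites <- trio %>%
    mutate(evaluable = complete,
           me = .data$evaluable & !mendelian_consistent(.data$child,
                                                        .data$mother,
                                                        .data$father),
           category = dplyr::case_when(
             !.data$me ~ NA_character_,
             .data$child == "0/1" & .data$mother == "0/0" &
               .data$father == "0/0" ~ "het_denovo",
             .data$child == "1/1" & .data$mother == "0/0" &
               .data$father == "0/0" ~ "hom_denovo",
             TRUE ~ "other"
           ))
  n_sites <- sum(sites$evaluable)
  n_err <- sum(sites$me)
  structure(list(
    mer = if (n_sites == 0) NA_real_ else n_err / n_sites,
    n_errors = n_err, n_sites = n_sites,
    het_denovo = sum(sites$category == "het_denovo", na.rm = TRUE),
    hom_denovo = sum(sites$category == "hom_denovo", na.rm = TRUE),
    other = sum(sites$category == "other", na.rm = TRUE),
    sites = sites
  ), class = "trio_report")
}

# TRUE when some pair of transmitted parental alleles explains the child.
mendelian_consistent <- function(child, mother, father) {
  al <- function(g) strsplit(g, "/", fixed = TRUE)
  ca <- al(child); ma <- al(mother); fa <- al(father)
  vapply(seq_along(child), function(i) {
    any(outer(ma[[i]], fa[[i]],
              Vectorize(function(m, f) {
                setequal_multiset(c(m, f), ca[[i]])
              })))
  }, logical(1))
}

setequal_multiset <- function(a, b) {
  identical(sort(a), sort(b))
}

#' @export
print.trio_report <- function(x, ...) {
  cat("<trio_report> MER=", round(100 * x$mer, 2), "% (", x$n_errors, "/",
      x$n_sites, "); het de novo ", x$het_denovo, ", hom de novo ",
      x$hom_denovo, ", other ", x$other, "\n", sep = "")
  invisible(x)
}

#' @rdname mendelian
#' @param x A `trio_report`.
#' @param ... Unused.
#' @export
glance.trio_report <- function(x, ...) {
  tibble(mer = x$mer, n_errors = x$n_errors, n_sites = x$n_sites,
         het_denovo = x$het_denovo, hom_denovo = x$hom_denovo,
         other = x$other)
}

#' Concordance stratified by breakpoint offset
#'
#' Bins matched pairs by the maximum breakpoint offset and computes the
#' concordance metrics per bin.
#'
#' @inheritParams concordance
#' @param bins Numeric cut points (left-closed; a final open bin to `Inf` is
#'   added automatically).
#' @return Tibble with one row per non-empty bin and the
#'   [glance.concordance_report()] columns.
#' @export
offset_stratified_concordance <- function(m, bins = c(0, 1, 10, 50),
                                          call_gts = NULL, truth_gts = NULL,
                                          exclude_nocall = FALSE) {
  edges <- sort(unique(c(bins, Inf)))
  pairs <- m$pairs
  bin_idx <- findInterval(pairs$max_offset, edges)
  purrr::map_dfr(sort(unique(bin_idx)), function(b) {
    sub <- structure(list(pairs = pairs[bin_idx == b, ],
                          unmatched_calls = m$unmatched_calls[0, ],
                          unmatched_truth = m$unmatched_truth[0, ]),
                     class = "match_result")
    rep <- concordance(sub, call_gts, truth_gts, exclude_nocall)
    dplyr::bind_cols(
      tibble(offset_min = edges[b],
             offset_max = edges[b + 1]),
      glance(rep))
  })
}
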