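# Breakpoint-proposal refinement for deletions in tandem repeats: a deletion
# of whole repeat units has ambiguous placement, so alternate placements
# shifted by the repeat period are proposed and the description whose
# simulated non-reference evidence lies closest to the actual evidence is
# selected.

#' Detect tandem-repeat context around a deletion
#'
#' Finds the smallest period `p <= |svlen|` such that the deleted sequence
#' plus `search_window` downstream bases is periodic with period `p` under at
#' most `max_mismatch` mismatching positions.
#'
#' @param v One-row `sv_tbl` (DEL).
#' @param genome Genome.
#' @param search_window Flanking bases included in the periodicity check.
#'   The default `|svlen|` is the smallest window that still permits a
#'   period equal to the deletion length (one whole-unit copy) while not
#'   reaching far past short repeat tracts.
#' @param max_mismatch Tolerated mismatch fraction. Copies of a real tandem
#'   repeat differ from each other at roughly twice the per-copy divergence,
#'   so the tolerance must sit well above that while staying far below the
#'   ~75% mismatch a random (non-periodic) offset produces; 0.2 accepts
#'   repeats up to ~10% copy divergence with a comfortable margin on short
#'   comparison windows.
#' @return Integer period, or `NA` if the context is not repetitive.
#' @export
detect_repeat_context <- function(v, genome, search_window = NULL,
                                  max_mismatch = 0.2) {
  stopifnot(v$svtype == "DEL")
  d <- abs(v$svlen)
  w <- search_window %||% d
  clen <- contig_length(genome, v$contig)
  start0 <- v$pos            # first deleted base, 0-based
  end0 <- min(clen, v$end + w)
  s <- strsplit(genome_substr(genome, v$contig, start0, end0), "")[[1]]
  n <- length(s)
  for (p in seq_len(d)) {
    if (n < 2 * p) break
    cmp <- s[seq_len(n - p)] != s[seq_len(n - p) + p]
    if (mean(cmp) <= max_mismatch) return(as.integer(p))
  }
  NA_integer_
}

#' Propose alternate placements for a deletion in a tandem repeat
#'
#' If the deleted region is periodic with period `p`, candidate descriptions
#' are the deletion shifted by multiples of `p` across the repeat tract
#' (accepted while the shifted deleted sequence still matches the original
#' under the mismatch tolerance), ordered nearest-to-original first and
#' truncated to `max_proposals` (the original is always included). On unique
#' sequence the proposal set is just the original.
#'
#' @inheritParams detect_repeat_context
#' @param max_proposals Maximum number of candidates, including the
#'   original.
#' @param cand_mismatch Mismatch tolerance for accepting a shifted
#'   placement as covering the repeat tract. Looser than the periodicity
#'   tolerance because copies of an imperfect repeat differ from each other
#'   at roughly twice the per-copy divergence; the final choice among
#'   candidates is made from the data by [select_description()], so this
#'   filter only needs to exclude placements that leave the tract.
#' @return A `proposal_set`: list with `original`, `candidates` (an
#'   `sv_tbl` with a `shift` column), and `repeat_period`.
#' @export
propose_alternates <- function(v, genome, max_proposals = 10L,
                               max_mismatch = 0.2, cand_mismatch = 0.25) {
  stopifnot(v$svtype == "DEL")
  p <- detect_repeat_context(v, genome, max_mismatch = max_mismatch)
  orig <- v %>% mutate(shift = 0L)
  if (is.na(p)) {
    return(structure(list(original = v, candidates = orig,
                          repeat_period = NA_integer_),
                     class = "proposal_set"))
  }
  d <- abs(v$svlen)
  w <- 2L * d
  clen <- contig_length(genome, v$contig)
  del_seq <- substr(v$ref, 2, nchar(v$ref))
  mk_candidate <- function(shift) {
    pos <- v$pos + shift
    if (pos - 1L < 1L || pos - 1L + nchar(v$ref) > clen) return(NULL)
    ref <- genome_substr(genome, v$contig, pos - 1L, pos - 1L + nchar(v$ref))
    if (grepl("N", ref)) return(NULL)
    shifted_del <- substr(ref, 2, nchar(ref))
    mm <- mean(strsplit(shifted_del, "")[[1]] != strsplit(del_seq, "")[[1]])
    if (mm > cand_mismatch) return(NULL)
    sv_tibble(paste0(v$variant_id, "_s", shift), v$contig, pos, ref,
              substr(ref, 1, 1)) %>% mutate(shift = as.integer(shift))
  }
  cands <- list(orig)
  for (a in seq_len(ceiling(w / p))) {
    for (sgn in c(-1L, 1L)) {
      if (length(cands) >= max_proposals) break
      cand <- mk_candidate(sgn * a * p)
      if (!is.null(cand)) cands[[length(cands) + 1]] <- cand
    }
    if (length(cands) >= max_proposals) break
  }
  cands <- bind_rows(cands) %>%
    dplyr::distinct(.data$pos, .data$ref, .data$alt, .keep_all = TRUE) %>%
    head(max_proposals)
  structure(list(original = v, candidates = cands, repeat_period = p),
            class = "proposal_set")
}

#' @export
print.proposal_set <- function(x, ...) {
  cat("<proposal_set> ", nrow(x$candidates), " candidate(s), period ",
      x$repeat_period, "\n", sep = "")
  invisible(x)
}

#' Select the best SV description among proposals
#'
#' Distances are computed in per-feature z-score space (scaling fit on the
#' pooled simulated rows): each candidate's distance is the minimum over the
#' HET and HOM_ALT class centroids of the Euclidean distance to the actual
#' feature vector extracted under that candidate's description. The
#' candidate with the smallest distance wins; ties prefer the original, then
#' the smaller position.
#'
#' @param ps A `proposal_set`.
#' @param actual_fvs Feature tibble, one row per candidate (actual data
#'   under each candidate description), in candidate order.
#' @param sim_rows Labeled simulated feature tibble with a `candidate`
#'   column (index into the candidate set) and HET/HOM_ALT labels.
#' @param features Feature subset used for the distance. The default pairs
#'   the realignment axis (`alt_fraction`) with one depth axis (`dhffc`):
#'   both are invariant to local coverage fluctuations (unlike raw counts,
#'   which would let sampling depth outvote placement), and using a single
#'   depth fold-change avoids triple-counting the depth signal through its
#'   near-duplicates `dhfc`/`dhbfc`, which would otherwise dominate the one
#'   realignment feature that actually distinguishes shifted placements.
#' @return List with `selected` (one-row `sv_tbl`), `distances` (tibble per
#'   candidate).
#' @export
select_description <- function(ps, actual_fvs, sim_rows,
                               features = c("alt_fraction", "dhffc")) {
  k <- nrow(ps$candidates)
  stopifnot(nrow(actual_fvs) == k)
  fm <- function(rows) as.matrix(rows[, features])
  scaler <- fit_scaler(fm(sim_rows))
  zs <- apply_scaler(fm(sim_rows), scaler)
  za <- apply_scaler(fm(actual_fvs), scaler)
  dist_k <- vapply(seq_len(k), function(i) {
    rows <- which(sim_rows$candidate == i)
    min(vapply(c("HET", "HOM_ALT"), function(z) {
      sel <- rows[sim_rows$label[rows] == z]
      if (length(sel) == 0) return(Inf)
      centroid <- colMeans(zs[sel, , drop = FALSE])
      sqrt(sum((za[i, ] - centroid)^2))
    }, numeric(1)))
  }, numeric(1))
  ord <- order(dist_k, ps$candidates$shift != 0L, ps$candidates$pos)
  sel <- ps$candidates[ord[1], ]
  list(selected = sel,
       distances = ps$candidates %>% mutate(distance = dist_k))
}

#' Refine deletion descriptions by simulation-guided proposal selection
#'
#' For each deletion, proposes alternate placements within its tandem-repeat
#' tract, simulates HET and HOM_ALT replicates for every candidate, extracts
#' the actual evidence under every candidate description, and keeps the
#' description whose simulated non-reference evidence is closest to the
#' actual data. Non-repetitive deletions and insertions pass through
#' unchanged.
#'
#' @inheritParams genotype_svs
#' @param max_proposals Maximum candidates per deletion.
#' @param n_replicates Simulated replicates per zygosity per candidate.
#' @return `sv_tbl` with refined coordinates and an `original_pos` column.
#' @export
refine_svs <- function(variants, alignments, genome, p, seed = 1,
                       max_proposals = 10L, n_replicates = 10L,
                       cfg = classifier_config(), config = realign_config()) {
  flank <- compute_flank(p)
  sflank <- compute_sim_flank(p, config)
  out <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    orig <- v %>% mutate(original_pos = v$pos)
    if (v$svtype != "DEL") return(orig)
    ps <- propose_alternates(v, genome, max_proposals = max_proposals)
    if (nrow(ps$candidates) == 1) return(orig)
    cand_data <- purrr::map(seq_len(nrow(ps$candidates)), function(ci) {
      cv <- ps$candidates[ci, ]
      cv_sv <- cv %>% select(-"shift")
      ctx <- allele_contexts(cv_sv, genome, flank)
      act <- extract_features(alignments, cv_sv, ctx, p, genome, config)
      sims <- purrr::map_dfr(c("HET", "HOM_ALT"), function(z) {
        zi <- match(z, zygosity_levels())
        purrr::map_dfr(seq_len(n_replicates), function(k) {
          reads <- simulate_replicate(
            cv_sv, genome, z, p, sflank,
            seed = derive_seed(seed, sum(utf8ToInt(cv_sv$variant_id)), zi, k))
          extract_features(reads, cv_sv, ctx, p, genome, config, label = z)
        })
      })
      list(actual = act, sims = sims %>% mutate(candidate = ci))
    })
    sel <- select_description(
      ps,
      purrr::map_dfr(cand_data, "actual"),
      purrr::map_dfr(cand_data, "sims"))
    sel$selected %>% select(-"shift") %>%
      mutate(variant_id = v$variant_id, original_pos = v$pos)
  })
  class(out) <- c("sv_tbl", setdiff(class(out), "sv_tbl"))
  out
}
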