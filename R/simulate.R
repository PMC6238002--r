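# Random cohort simulator with known ground truth. Emulates the
# statistical structure of an edited-zygote cohort: per-position edit
# probabilities inside the editing window, at bystander protospacer
# positions and across the proximal flanks (with optional 5'-TC-3'
# enrichment), a product-purity mixture, and a per-allele deletion
# probability with a length distribution.

#' Simulation profile for one editor
#'
#' @param editor an [editor_spec()].
#' @param p_on_target per-position edit probability at target bases inside
#'   the editing window.
#' @param p_bystander per-position probability at target bases in the
#'   protospacer outside the window.
#' @param p_proximal per-position probability at flank target bases within
#'   the proximal radius.
#' @param tc_enrichment multiplier (>= 1) applied to `p_proximal` at flank
#'   cytosines in 5'-TC-3' context (either strand).
#' @param purity probability mixture over product classes, named
#'   `anticipated`, `opposite_strand`, `other_substitution`; must sum to 1.
#' @param p_deletion per-allele probability of carrying one deletion.
#' @param deletion_len_dist probability weights over deletion lengths
#'   1..`length(deletion_len_dist)` (default geometric-ish over 1-10).
#' @return object of class `be_sim_profile`.
#' @export
sim_profile <- function(editor,
                        p_on_target = 0.5,
                        p_bystander = 0.05,
                        p_proximal = 0.002,
                        tc_enrichment = 3,
                        purity = c(anticipated = 0.9, opposite_strand = 0.05,
                                   other_substitution = 0.05),
                        p_deletion = 0.1,
                        deletion_len_dist = 0.5^(1:10)) {
  stopifnot(inherits(editor, "editor_spec"))
  probs <- c(p_on_target, p_bystander, p_proximal, p_deletion)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("probabilities must lie in [0, 1]", class = "be_invalid_spec")
  }
  if (tc_enrichment < 1) {
    rlang::abort("tc_enrichment must be >= 1", class = "be_invalid_spec")
  }
  need <- c("anticipated", "opposite_strand", "other_substitution")
  if (!setequal(names(purity), need) || abs(sum(purity) - 1) > 1e-8 ||
      any(purity < 0)) {
    rlang::abort("purity must be a probability mixture over anticipated/opposite_strand/other_substitution",
                 class = "be_invalid_spec")
  }
  deletion_len_dist <- deletion_len_dist / sum(deletion_len_dist)
  structure(
    list(editor = editor, p_on_target = p_on_target,
         p_bystander = p_bystander, p_proximal = p_proximal,
         tc_enrichment = tc_enrichment, purity = purity[need],
         p_deletion = p_deletion, deletion_len_dist = deletion_len_dist),
    class = "be_sim_profile"
  )
}

# candidate edit sites on the locus, per region, for target-base (tb) and
# complement-base (ctb, opposite strand) positions
sim_sites <- function(locus, editor) {
  n <- nchar(locus$reference_seq)
  pos <- seq_len(n)
  base <- strsplit(locus$reference_seq, "")[[1]]
  p <- pos - locus$protospacer_start + 1L
  region <- region_of_pos(p, editor, locus$protospacer_len, locus$proximal_radius)
  prev <- c(NA, base[-n]); nxt <- c(base[-1], NA)
  tibble::tibble(
    ref_pos = pos, base = base, region = region,
    # TC context: protospacer-strand C preceded by T, or opposite-strand C
    # (a G here) whose 5' neighbor on that strand is T (a 3' A here)
    tc = (base == editor$target_base & !is.na(prev) & prev == "T") |
         (base == complement_base(editor$target_base) & !is.na(nxt) & nxt == "A")
  )
}

#' Simulate a cohort of edited alleles with ground truth
#'
#' Each allele is built by sampling substitution events at target-base
#' positions per region, drawing a product class for each event from the
#' purity mixture (opposite-strand events are realized at the nearest
#' complement-base position in the same region), optionally adding one
#' deletion, and applying all events 3' to 5' to the reference.
#' Deterministic given `seed`.
#'
#' @param locus a [target_locus()].
#' @param profile a [sim_profile()].
#' @param n_alleles number of alleles to simulate.
#' @param seed integer seed.
#' @param editor_name editor label written into the cohort tables
#'   (defaults to the profile's editor name).
#' @return list with `alleles` (tibble `allele_id`, `editor_name`, `seq`)
#'   and `ground_truth` (tibble of injected events with intended
#'   region/product labels).
#' @export
simulate_cohort <- function(locus, profile, n_alleles, seed = 1L,
                            editor_name = profile$editor$name) {
  stopifnot(inherits(locus, "target_locus"), inherits(profile, "be_sim_profile"))
  editor <- profile$editor
  set.seed(as.integer(seed))
  sites <- sim_sites(locus, editor)
  tb <- editor$target_base; ctb <- complement_base(tb)
  pb <- editor$product_base; cpb <- complement_base(pb)
  other_bases <- setdiff(c("A", "C", "G", "T"), c(tb, pb))

  tgt <- sites[sites$base == tb & sites$region != "out_of_range", ]
  opp <- sites[sites$base == ctb & sites$region != "out_of_range", ]
  p_site <- function(region, tc) {
    base_p <- dplyr::case_when(
      region == "on_target" ~ profile$p_on_target,
      region == "bystander" ~ profile$p_bystander,
      region == "proximal_off_target" ~ profile$p_proximal
    )
    pmin(1, base_p * ifelse(region == "proximal_off_target" & tc,
                            profile$tc_enrichment, 1))
  }
  p_tgt <- p_site(tgt$region, tgt$tc)

  alleles <- vector("list", n_alleles)
  truth <- vector("list", n_alleles)
  for (i in seq_len(n_alleles)) {
    id <- sprintf("sim/%s_%04d", editor_name, i)
    hit <- tgt[stats::runif(nrow(tgt)) < p_tgt, ]
    ev <- NULL
    if (nrow(hit) > 0) {
      cls <- sample(names(profile$purity), nrow(hit), replace = TRUE,
                    prob = profile$purity)
      used_opp <- integer(0)
      ev <- purrr::map_dfr(seq_len(nrow(hit)), function(k) {
        if (cls[k] == "anticipated") {
          tibble::tibble(kind = "substitution", ref_pos = hit$ref_pos[k],
                         ref = tb, alt = pb)
        } else if (cls[k] == "other_substitution") {
          tibble::tibble(kind = "substitution", ref_pos = hit$ref_pos[k],
                         ref = tb, alt = sample(other_bases, 1))
        } else {
          # realize opposite-strand deamination at the nearest unused
          # complement-base site in the same region; fall back to an
          # other-substitution when none exists
          cand <- opp[opp$region == hit$region[k] &
                        !(opp$ref_pos %in% used_opp), ]
          if (nrow(cand) == 0) {
            tibble::tibble(kind = "substitution", ref_pos = hit$ref_pos[k],
                           ref = tb, alt = sample(other_bases, 1))
          } else {
            j <- which.min(abs(cand$ref_pos - hit$ref_pos[k]))
            used_opp <<- c(used_opp, cand$ref_pos[j])
            tibble::tibble(kind = "substitution", ref_pos = cand$ref_pos[j],
                           ref = ctb, alt = cpb)
          }
        }
      })
      ev <- dplyr::distinct(ev, .data$ref_pos, .keep_all = TRUE)
    }
    if (stats::runif(1) < profile$p_deletion) {
      len <- sample(seq_along(profile$deletion_len_dist), 1,
                    prob = profile$deletion_len_dist)
      start <- locus$protospacer_start +
        sample.int(locus$protospacer_len - len + 1L, 1) - 1L
      del <- tibble::tibble(
        kind = "deletion", ref_pos = start,
        ref = substring(locus$reference_seq, start, start + len - 1L),
        alt = ""
      )
      # drop substitutions swallowed by the deletion
      if (!is.null(ev)) {
        ev <- ev[ev$ref_pos < start | ev$ref_pos > start + len - 1L, ]
      }
      ev <- dplyr::bind_rows(ev, del)
    }
    if (is.null(ev) || nrow(ev) == 0) {
      alleles[[i]] <- tibble::tibble(allele_id = id, editor_name = editor_name,
                                     seq = locus$reference_seq)
      next
    }
    ev <- ev |>
      dplyr::mutate(length = dplyr::if_else(.data$kind == "insertion",
                                            nchar(.data$alt), nchar(.data$ref))) |>
      dplyr::arrange(.data$ref_pos)
    # canonicalize injected events to the caller's left-most form so the
    # ground truth uses the same coordinates the caller reports
    ev <- canonicalize_events(ev, locus$reference_seq)
    prod <- classify_product(ev$kind, ev$ref, ev$alt, editor)
    truth[[i]] <- ev |>
      dplyr::mutate(
        allele_id = id, editor_name = editor_name,
        region = classify_region(.data$ref_pos, .data$kind, .data$length,
                                 locus, editor),
        product = prod$product, edited_strand = prod$edited_strand
      ) |>
      dplyr::select("allele_id", "editor_name", "kind", "ref_pos", "ref",
                    "alt", "length", "region", "product", "edited_strand")
    alleles[[i]] <- tibble::tibble(
      allele_id = id, editor_name = editor_name,
      seq = apply_mutations(locus$reference_seq, ev)
    )
  }
  list(alleles = dplyr::bind_rows(alleles),
       ground_truth = dplyr::bind_rows(truth))
}
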