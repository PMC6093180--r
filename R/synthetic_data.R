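#' Specification of a synthetic exon study
#'
#' Defines the study conditions for the synthetic generator: group
#' sizes, flank geometry, intron background composition, the planted
#' U-rich window (with optional bipartite alternating-U substructure),
#' AGEZ length distributions, branch-point planting distances, optional
#' hairpin plants, and the linear coupling between upstream-flank PU and
#' exon-usage log2fold.  Defaults emulate the architecture reported for
#' splicing-factor-activated exons: an AGEZ 1.51x the control mean,
#' branch points planted ~52 nt (activated) versus ~25 nt (control)
#' upstream of the 3'ss, U enrichment over -18..-50, and a negative
#' PU-log2fold coupling (depletion of an activator lowers inclusion).
#'
#' @param n_activated,n_repressed,n_control group sizes.
#' @param flank_len,exon_len context geometry in nt.
#' @param background_freqs intron background composition (A, C, G, U).
#' @param u_window signed acceptor-frame interval carrying the planted
#'   U excess (activated) or U depletion (repressed).
#' @param excess_U probability that a window position is overwritten by
#'   U (activated group).
#' @param bipartite alternate high/low U positions and tilt the non-U
#'   background C-rich in the 3'-proximal half and G-rich in the
#'   5'-distal half, mimicking bipartite polypyrimidine tracts.
#' @param alternation factor applied to `excess_U` at the low positions
#'   of the alternating pattern.
#' @param u_depletion_repressed fraction of background U mass moved to G
#'   inside the window for repressed exons.
#' @param agez_mean_control mean AGEZ length (nt) of the control group.
#' @param agez_ratio_activated,agez_ratio_repressed multipliers of the
#'   control mean for the other groups.
#' @param bp_distance_mean,bp_distance_sd named per-group branch-point
#'   distance distributions (nt upstream of the 3'ss).
#' @param bp_consensus planted branch-point heptamer (must contain no
#'   AG dinucleotide); `bp_branch_offset` marks its branch adenine.
#' @param hairpin_plant `NULL`, or a named list per group of
#'   `list(stem =, loop =, window = c(lo, hi))` describing a planted
#'   hairpin in the upstream flank (`2*stem + loop` must equal the
#'   window width).
#' @param coupling_slope,coupling_noise_sd log2fold model for activated
#'   exons: `slope * mean_flank_pu(acceptor, pu_coupling_window) +
#'   N(0, sd)`.
#' @param pu_coupling_window signed window for the coupling PU mean.
#' @param plant_agez,plant_bp disable individual plants (useful for
#'   background-composition checks).
#' @param seed RNG seed used by [generate_study()].
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_activated = 120L, n_repressed = 20L,
                           n_control = 500L,
                           flank_len = 150L, exon_len = 80L,
                           background_freqs = c(A = 0.27, C = 0.21,
                                                G = 0.21, U = 0.31),
                           u_window = c(-50, -18), excess_U = 0.25,
                           bipartite = TRUE, alternation = 0.75,
                           u_depletion_repressed = 0.5,
                           agez_mean_control = 37,
                           agez_ratio_activated = 1.51,
                           agez_ratio_repressed = 1.0,
                           bp_distance_mean = c(activated = 52,
                                                repressed = 24,
                                                control = 25),
                           bp_distance_sd = c(activated = 8,
                                              repressed = 6, control = 6),
                           bp_consensus = "UACUAAC",
                           bp_branch_offset = 6L,
                           hairpin_plant = NULL,
                           coupling_slope = -27, coupling_noise_sd = 0.35,
                           pu_coupling_window = c(-100, -4),
                           plant_agez = TRUE, plant_bp = TRUE,
                           seed = 1L) {
  if (any(c(n_activated, n_repressed, n_control) < 0))
    stop("group sizes must be >= 0")
  if (abs(sum(background_freqs) - 1) > 1e-8 || any(background_freqs < 0))
    stop("background_freqs must be a distribution over A, C, G, U")
  if (!all(RNA_LETTERS %in% names(background_freqs)))
    stop("background_freqs must be named A, C, G, U")
  if (excess_U < 0 || excess_U > 1) stop("excess_U must lie in [0, 1]")
  if (flank_len < 40) stop("flank_len too short for the planted features")
  if (max(abs(u_window)) > flank_len) stop("u_window outside the flank")
  bp <- .to_rna(bp_consensus)
  if (grepl("AG", bp, fixed = TRUE))
    stop("bp_consensus must not contain an AG dinucleotide")
  if (substr(bp, bp_branch_offset, bp_branch_offset) != "A")
    stop("bp_branch_offset must point at an adenine of the consensus")
  if (!is.null(hairpin_plant)) {
    for (g in names(hairpin_plant)) {
      hp <- hairpin_plant[[g]]
      wlen <- abs(diff(sort(hp$window))) + 1L
      if (2L * hp$stem + hp$loop != wlen)
        stop("hairpin 2*stem + loop must equal the window width")
      if (any(hp$window >= 0)) stop("hairpin window must be upstream")
    }
  }
  structure(as.list(environment()), class = "SyntheticSpec")
}

# per-position sampling distributions for the upstream flank of one
# group; returns a flank_len x 4 matrix of probabilities
.upstream_dists <- function(spec, group) {
  L <- spec$flank_len
  bg <- spec$background_freqs[RNA_LETTERS]
  mat <- matrix(rep(bg, each = L), L, 4, dimnames = list(NULL, RNA_LETTERS))
  w <- sort(spec$u_window)
  wpos <- seq(w[1], w[2])
  widx <- L + wpos + 1L
  keep <- widx >= 1 & widx <= L
  wpos <- wpos[keep]; widx <- widx[keep]
  if (!length(widx)) return(mat)
  if (group == "activated" && spec$excess_U > 0) {
    mid <- ceiling(mean(w))
    for (j in seq_along(widx)) {
      p <- wpos[j]
      base <- bg
      if (spec$bipartite) {
        # 3'-proximal half C-tilted, 5'-distal half G-tilted (non-U)
        shift <- 0.5 * base[["G"]]
        if (p > mid) {  # proximal
          base[["C"]] <- base[["C"]] + shift; base[["G"]] <- base[["G"]] - shift
        } else {
          shiftc <- 0.5 * base[["C"]]
          base[["G"]] <- base[["G"]] + shiftc; base[["C"]] <- base[["C"]] - shiftc
        }
        e <- if ((abs(p) %% 2L) == 0L) spec$excess_U
             else spec$excess_U * spec$alternation
      } else {
        e <- spec$excess_U
      }
      mat[widx[j], ] <- (1 - e) * base + e * c(A = 0, C = 0, G = 0, U = 1)
    }
  } else if (group == "repressed" && spec$u_depletion_repressed > 0) {
    moved <- spec$u_depletion_repressed * bg[["U"]]
    base <- bg
    base[["U"]] <- base[["U"]] - moved
    base[["G"]] <- base[["G"]] + moved
    mat[widx, ] <- matrix(rep(base, each = length(widx)), ncol = 4)
  }
  mat
}

.draw_from <- function(dist_row) {
  sample(RNA_LETTERS, 1L, prob = dist_row)
}

.draw_seq <- function(n, freqs) {
  sample(RNA_LETTERS, n, replace = TRUE, prob = freqs[RNA_LETTERS])
}

# sequential no-AG enforcement over zone indices (1-based ascending);
# protected positions are never rewritten
.enforce_no_ag <- function(s, zone, protected, dists) {
  for (pass in 1:1000) {
    viol <- 0L
    for (i in zone) {
      if (i < 2) next
      if (s[i] == "G" && s[i - 1] == "A") { viol <- i; break }
    }
    if (viol == 0L) return(s)
    i <- viol
    if (!protected[i]) {
      pr <- dists[i, ]; pr[["G"]] <- 0
      s[i] <- sample(RNA_LETTERS, 1L, prob = pr)
    } else if (!protected[i - 1]) {
      pr <- dists[i - 1, ]; pr[["A"]] <- 0
      s[i - 1] <- sample(RNA_LETTERS, 1L, prob = pr)
    } else {
      stop("internal: AG formed between two protected positions")
    }
  }
  stop("internal: no-AG enforcement did not converge")
}

.draw_hairpin <- function(hp, freqs) {
  for (try in 1:1000) {
    arm <- .draw_seq(hp$stem, freqs)
    loop <- .draw_seq(hp$loop, freqs)
    arm2 <- .split_chars(.revcomp_rna(paste(arm, collapse = "")))
    full <- c(arm, loop, arm2)
    if (!grepl("AG", paste(full, collapse = ""), fixed = TRUE))
      return(full)
  }
  stop("internal: could not draw an AG-free hairpin")
}

#' Generate one synthetic spliced context
#'
#' Builds the upstream flank from the group's per-position background
#' (U window overlaid for activated/repressed groups), plants the
#' branch-point heptamer at a drawn 3'ss distance, forces the upstream
#' AG that terminates the drawn AGEZ and resamples any AG dinucleotide
#' inside the zone, writes the 3'ss AG and 5'ss GU, and optionally
#' embeds a complementary hairpin.  Every planted feature in the
#' returned truth row is literally verifiable on the emitted string.
#'
#' @param spec a [synthetic_spec()].
#' @param group `"activated"`, `"repressed"` or `"control"`.
#' @param exon_id identifier for the emitted context.
#' @return list with elements `context` (a `SplicedContext`, log2fold
#'   unset) and `truth` (one-row data.frame).
#' @export
generate_context <- function(spec, group, exon_id = "syn1") {
  L <- spec$flank_len
  dists <- .upstream_dists(spec, group)
  bg <- spec$background_freqs
  hp <- if (!is.null(spec$hairpin_plant)) spec$hairpin_plant[[group]]
        else NULL
  hp_idx <- if (!is.null(hp)) {
    w <- sort(hp$window); (L + w[1] + 1L):(L + w[2] + 1L)
  } else integer()

  agez_mean <- spec$agez_mean_control *
    switch(group, activated = spec$agez_ratio_activated,
           repressed = spec$agez_ratio_repressed, control = 1.0)
  # joint draw of AGEZ length and BP distance with geometric feasibility
  for (try in 1:500) {
    g <- if (spec$plant_agez) {
      max(4L, min(L - 12L, round(rgamma(1, shape = 3,
                                        scale = agez_mean / 3))))
    } else NA_integer_
    d <- if (spec$plant_bp) {
      mu <- spec$bp_distance_mean[[group]]
      sdv <- spec$bp_distance_sd[[group]]
      max(10L, min(min(95L, L - 10L), round(rnorm(1, mu, sdv))))
    } else NA_integer_
    used <- integer()
    if (!is.na(g)) used <- c(used, (L - g - 3L):(L - g - 2L))
    if (!is.na(d)) {
      k <- L - d + 1L
      moff <- spec$bp_branch_offset
      mstart <- k - moff + 1L
      mend <- k + (nchar(spec$bp_consensus) - moff)
      if (mstart < 1 || mend > L - 2L) next
      midx <- mstart:mend
      if (!is.na(g) && length(intersect(midx, (L - g - 3L):(L - g - 2L))))
        next
      used <- c(used, midx)
    }
    if (length(hp_idx) && length(intersect(hp_idx, used))) next
    if (length(hp_idx) && max(hp_idx) > L - 2L) next
    break
  }

  up <- vapply(seq_len(L), function(i) .draw_from(dists[i, ]), "")
  protected <- logical(L)
  if (!is.na(d)) {
    up[midx] <- .split_chars(spec$bp_consensus)
    protected[midx] <- TRUE
  }
  if (length(hp_idx)) {
    up[hp_idx] <- .draw_hairpin(hp, bg)
    protected[hp_idx] <- TRUE
  }
  if (!is.na(g)) {
    up[L - g - 3L] <- "A"; up[L - g - 2L] <- "G"
    protected[c(L - g - 3L, L - g - 2L)] <- TRUE
  }
  up[L - 1L] <- "A"; up[L] <- "G"
  protected[c(L - 1L, L)] <- TRUE
  if (!is.na(g) && g > 0) {
    zone <- (L - g - 1L):(L - 2L)
    up <- .enforce_no_ag(up, zone, protected, dists)
  }

  exon <- .draw_seq(spec$exon_len, bg)
  down <- .draw_seq(L, bg)
  down[1L] <- "G"; down[2L] <- "U"

  ctx <- spliced_context(exon_id = exon_id,
                         upstream = paste(up, collapse = ""),
                         exon = paste(exon, collapse = ""),
                         downstream = paste(down, collapse = ""),
                         group = group)
  truth <- data.frame(
    exon_id = exon_id, group = group,
    agez_len = if (is.na(g)) NA_integer_ else g,
    upstream_ag_pos = if (is.na(g)) NA_integer_ else -(g + 3L),
    bp_pos = if (is.na(d)) NA_integer_ else -d,
    bp_motif_start = if (is.na(d)) NA_integer_ else mstart - L - 1L,
    u_window_lo = if (group %in% c("activated", "repressed"))
      min(spec$u_window) else NA_integer_,
    u_window_hi = if (group %in% c("activated", "repressed"))
      max(spec$u_window) else NA_integer_,
    hairpin_lo = if (length(hp_idx)) min(hp_idx) - L - 1L else NA_integer_,
    hairpin_hi = if (length(hp_idx)) max(hp_idx) - L - 1L else NA_integer_,
    pu_upstream = NA_real_, log2fold_noiseless = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.na(g)) {
    got <- agez_length(ctx)
    if (got$censored || got$agez_len != g)
      stop("internal: planted AGEZ not recovered on the emitted string")
  }
  list(context = ctx, truth = truth)
}

#' Generate a synthetic exon study
#'
#' Draws all three groups from a [synthetic_spec()] (RNG seeded from
#' `spec$seed`, so a fixed spec yields byte-identical studies), assigns
#' log2fold values to activated exons by the linear PU coupling model
#' (negative slope: stronger upstream single-strandedness, stronger
#' inclusion loss on activator depletion), and returns the contexts
#' together with the planted-truth table.
#'
#' @param spec a [synthetic_spec()].
#' @param model [energy_model()] used for the coupling PU means.
#' @return object of class `SyntheticStudy`: list with `contexts`,
#'   `truth` (one row per context) and `spec`.
#' @export
generate_study <- function(spec, model = energy_model()) {
  set.seed(spec$seed)
  contexts <- list(); truths <- list()
  plan <- c(rep("activated", spec$n_activated),
            rep("repressed", spec$n_repressed),
            rep("control", spec$n_control))
  ids <- sprintf("syn_%s_%03d", plan,
                 unlist(lapply(table(factor(plan, levels = unique(plan))),
                               seq_len)))
  for (i in seq_along(plan)) {
    gc <- generate_context(spec, plan[i], exon_id = ids[i])
    contexts[[i]] <- gc$context
    truths[[i]] <- gc$truth
  }
  truth <- do.call(rbind, truths)
  # PU-log2fold coupling for activated exons
  for (i in seq_along(plan)) {
    if (plan[i] == "activated") {
      pu <- mean_flank_pu(contexts[[i]], "acceptor",
                          spec$pu_coupling_window, model)
      noiseless <- spec$coupling_slope * pu
      lf <- noiseless + rnorm(1, 0, spec$coupling_noise_sd)
      contexts[[i]]$log2fold <- lf
      truth$pu_upstream[i] <- pu
      truth$log2fold_noiseless[i] <- noiseless
    } else if (plan[i] == "repressed") {
      contexts[[i]]$log2fold <- rnorm(1, 1.0, 0.4)
    }
  }
  structure(list(contexts = contexts, truth = truth, spec = spec),
            class = "SyntheticStudy")
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf("SyntheticStudy: %d contexts (%s)\n", length(x$contexts),
              paste(sprintf("%s=%d", names(table(x$truth$group)),
                            table(x$truth$group)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Contexts go to the structured-header FASTA dialect, the truth table
#' to a TSV; both byte-deterministic.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_context_fasta(study$contexts, file.path(dir, "contexts.fa"))
  .write_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
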