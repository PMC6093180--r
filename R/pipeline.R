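# Deterministic TSV writing: fixed column order, "%.10g" numbers, no
# quoting, LF newlines.  All report files go through these helpers so
# that runs with the same seed are byte-identical.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%d", as.integer(round(x))), sprintf("%.10g", x)))
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con,
               sep = "\n")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run.  Signed windows may be
#' given in either order; they are normalised (with a logged note) so
#' that, e.g., a branch-point window -40..-18 and -18..-40 are the same
#' configuration.
#'
#' @param contexts list of `SplicedContext` (e.g. from
#'   [extract_contexts()], [read_context_fasta()] or a
#'   [generate_study()]); alternatively give `context_fasta`.
#' @param context_fasta path to a context FASTA (see
#'   [read_context_fasta()]); ignored when `contexts` is given.
#' @param seed RNG seed; required, no unseeded runs.
#' @param outdir report directory.
#' @param acceptor_range,donor_range profiled signed position ranges.
#' @param bp_window branch-point-region PU window (acceptor frame).
#' @param flank_window_up,flank_window_down per-exon PU summary windows.
#' @param model [energy_model()] parameters.
#' @param n_shuffles shuffled controls generated per exon.
#' @param bg_shuffles,bg_exons of those, how many shuffles per exon and
#'   how many exons per group enter the background PU profile
#'   (subsampling keeps desk-scale runtime; `bg_exons = NULL` uses all).
#' @param kmer_k,kmer_range k-mer enrichment scan settings.
#' @param group_pairs list of 2-vectors of group names to compare;
#'   `NULL` compares every pair present.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(contexts = NULL, context_fasta = NULL,
                       seed, outdir,
                       acceptor_range = c(-100, 10),
                       donor_range = c(-10, 100),
                       bp_window = c(-40, -18),
                       flank_window_up = c(-100, -4),
                       flank_window_down = c(7, 100),
                       model = energy_model(),
                       n_shuffles = 100L, bg_shuffles = 3L,
                       bg_exons = 50L,
                       kmer_k = 5L, kmer_range = c(-100, -4),
                       group_pairs = NULL) {
  if (missing(seed) || !.is_count(seed)) stop("a numeric seed is required")
  if (missing(outdir)) stop("outdir is required")
  if (is.null(contexts) && is.null(context_fasta))
    stop("provide contexts or context_fasta")
  norm <- function(w, nm) {
    if (w[1] > w[2]) message("normalising reversed window ", nm, ": ",
                             w[1], "..", w[2], " -> ", w[2], "..", w[1])
    sort(w)
  }
  structure(list(
    contexts = contexts, context_fasta = context_fasta,
    seed = as.integer(seed), outdir = outdir,
    acceptor_range = norm(acceptor_range, "acceptor_range"),
    donor_range = norm(donor_range, "donor_range"),
    bp_window = norm(bp_window, "bp_window"),
    flank_window_up = norm(flank_window_up, "flank_window_up"),
    flank_window_down = norm(flank_window_down, "flank_window_down"),
    model = model, n_shuffles = as.integer(n_shuffles),
    bg_shuffles = as.integer(bg_shuffles),
    bg_exons = if (is.null(bg_exons)) NULL else as.integer(bg_exons),
    kmer_k = as.integer(kmer_k), kmer_range = kmer_range,
    group_pairs = group_pairs), class = "RunConfig")
}

# per-exon x position pentamer PU matrix (rows = exons)
.pu_matrix <- function(contexts, frame, positions, model) {
  m <- matrix(NA_real_, length(contexts), length(positions),
              dimnames = list(vapply(contexts, `[[`, "", "exon_id"),
                              positions))
  for (i in seq_along(contexts))
    m[i, ] <- .context_position_pu(contexts[[i]], frame, positions, model)
  m
}

.profile_from_matrix <- function(m, frame, positions) {
  ns <- colSums(!is.na(m))
  structure(list(frame = frame, positions = positions,
                 mean_pu = setNames(colMeans(m, na.rm = TRUE), positions),
                 n_per_position = ns),
            class = "PUProfile")
}

#' Per-exon 3'ss architecture feature table
#'
#' One row per context: AGEZ length (and censoring flag), best
#' branch-point distance and score, polypyrimidine metrics, splice-site
#' strengths, and the windowed PU summaries used by the group
#' statistics.
#'
#' @param contexts list of `SplicedContext`.
#' @param config a [run_config()].
#' @param bp_pwm branch-point PWM (default [default_bp_pwm()]).
#' @param ss_pwms splice-site PWMs (default: estimated from the control
#'   group, or from all contexts when fewer than 5 controls).
#' @return data.frame.
#' @export
exon_feature_table <- function(contexts, config,
                               bp_pwm = default_bp_pwm(),
                               ss_pwms = NULL) {
  if (is.null(ss_pwms)) {
    ctrl <- Filter(function(c) c$group == "control", contexts)
    src <- if (length(ctrl) >= 5) ctrl else contexts
    ss_pwms <- splice_site_pwms(src)
  }
  rows <- lapply(contexts, function(ctx) {
    ag <- agez_length(ctx)
    bp <- score_bp_candidates(ctx, bp_pwm)
    ppt <- ppt_metrics(ctx, window = config$flank_window_up)
    ss <- splice_site_strength(ctx, ss_pwms$acceptor, ss_pwms$donor)
    data.frame(
      exon_id = ctx$exon_id, group = ctx$group, log2fold = ctx$log2fold,
      agez_len = ag$agez_len, agez_censored = ag$censored,
      best_bp_distance = if (bp$no_candidates) NA_integer_
                         else bp$best$distance,
      best_bp_score = if (bp$no_candidates) NA_real_ else bp$best$score,
      frac_U = ppt$frac_U, frac_pyrimidine = ppt$frac_pyrimidine,
      acceptor_score = unname(ss["acceptor_score"]),
      donor_score = unname(ss["donor_score"]),
      pu_up = mean_flank_pu(ctx, "acceptor", config$flank_window_up,
                            config$model),
      pu_down = mean_flank_pu(ctx, "donor", config$flank_window_down,
                              config$model),
      pu_bp_window = mean_flank_pu(ctx, "acceptor", config$bp_window,
                                   config$model),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.gc_to_list <- function(gc) {
  out <- list(statistic = unname(gc$statistic[1]),
              statistic_name = names(gc$statistic)[1],
              p_value = gc$p_value, n1 = gc$n1, n2 = gc$n2,
              method = gc$method)
  if (!is.null(gc$means)) out$means <- unname(gc$means)
  if (!is.null(gc$df)) out$df <- gc$df
  out
}

#' Group statistics over a feature table
#'
#' For every configured group pair: Wilcoxon-Mann-Whitney comparisons of
#' AGEZ length, best branch-point distance and the windowed PU
#' summaries; optionally per-position PU WMW tracks (raw and BH-adjusted
#' within each track).  For every group carrying log2fold values:
#' Pearson correlations of the upstream and downstream PU summaries
#' with log2fold, and of AGEZ length with upstream PU.  Groups with
#' fewer than 2 members are skipped with a warning; correlation blocks
#' are marked `"not computed"` where log2fold is absent.
#'
#' @param features an [exon_feature_table()].
#' @param config a [run_config()].
#' @param pu_tracks optional named list of per-group exon x position PU
#'   matrices (acceptor frame) for the per-position tracks.
#' @return nested list (serialisable to JSON).
#' @export
compare_groups <- function(features, config, pu_tracks = NULL) {
  groups <- unique(features$group)
  sizes <- table(features$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping group(s) with n < 2: ", paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  if (length(groups) < 2) stop("need at least 2 groups with n >= 2")
  pairs <- config$group_pairs
  if (is.null(pairs)) {
    pairs <- list()
    gs <- sort(groups)
    for (i in seq_along(gs)) for (j in seq_along(gs))
      if (i < j) pairs[[length(pairs) + 1L]] <- c(gs[i], gs[j])
  }
  feat_cols <- c("agez_len", "best_bp_distance", "pu_up", "pu_down",
                 "pu_bp_window")
  comparisons <- list()
  for (pr in pairs) {
    if (!all(pr %in% groups)) next
    a <- features[features$group == pr[1], , drop = FALSE]
    b <- features[features$group == pr[2], , drop = FALSE]
    block <- list()
    for (fc in feat_cols) {
      x <- a[[fc]]; y <- b[[fc]]
      if (sum(!is.na(x)) < 1 || sum(!is.na(y)) < 1) next
      block[[fc]] <- .gc_to_list(mann_whitney_u(x, y))
    }
    if (!is.null(pu_tracks) && all(pr %in% names(pu_tracks))) {
      ma <- pu_tracks[[pr[1]]]; mb <- pu_tracks[[pr[2]]]
      p <- vapply(seq_len(ncol(ma)), function(k) {
        x <- ma[, k]; y <- mb[, k]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (!length(x) || !length(y)) return(NA_real_)
        mann_whitney_u(x, y)$p_value
      }, numeric(1))
      q <- rep(NA_real_, length(p))
      q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
      block$per_position_track <- list(
        positions = as.integer(colnames(ma)), p_raw = p, q_bh = q)
    }
    comparisons[[paste(pr, collapse = "_vs_")]] <- block
  }
  correlations <- list()
  for (g in groups) {
    gf <- features[features$group == g, , drop = FALSE]
    ok <- !is.na(gf$log2fold)
    if (sum(ok) < 3) {
      correlations[[g]] <- "not computed (log2fold absent)"
      next
    }
    gf <- gf[ok, , drop = FALSE]
    correlations[[g]] <- list(
      pu_up_vs_log2fold = .gc_to_list(correlation(gf$pu_up, gf$log2fold)),
      pu_down_vs_log2fold = .gc_to_list(correlation(gf$pu_down,
                                                    gf$log2fold)),
      agez_vs_pu_up = .gc_to_list(correlation(gf$agez_len, gf$pu_up)))
  }
  list(group_sizes = as.list(sizes), comparisons = comparisons,
       correlations = correlations)
}

.profile_df <- function(profile, group, kind) {
  data.frame(frame = profile$frame, group = group, kind = kind,
             position = profile$positions,
             mean_pu = unname(profile$mean_pu),
             n = unname(profile$n_per_position),
             stringsAsFactors = FALSE)
}

.composition_df <- function(comp, group) {
  do.call(rbind, lapply(seq_along(comp$positions), function(i) {
    data.frame(group = group, frame = comp$frame,
               position = comp$positions[i], letter = RNA_LETTERS,
               count = comp$counts[i, ], freq = comp$freqs[i, ],
               ci_low = comp$ci_low[i, ], ci_high = comp$ci_high[i, ],
               info_bits = comp$info_bits[i], n = comp$n[i],
               stringsAsFactors = FALSE)
  }))
}

#' Run the full 3'ss architecture pipeline
#'
#' Orchestrates extract -> features -> composition -> PU profiles (real
#' and shuffled background) -> k-mer scan -> group statistics, writing a
#' deterministic report bundle: `features.tsv`, `composition.tsv`,
#' `pu_profile.tsv`, `kmers.tsv`, `stats.json`, `provenance.json` and
#' `run.log`.  Runs with identical configuration and seed are
#' byte-identical.  Any stage error aborts the run, names the stage,
#' and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return the stats list, invisibly; the report bundle is written to
#'   `config$outdir`.
#' @export
run_profile <- function(config) {
  if (!inherits(config, "RunConfig")) stop("config must be a run_config()")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  logline <- character()
  stage <- "setup"
  on_fail <- function(e) {
    unlink(file.path(outdir, basename(written)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    set.seed(config$seed)
    stage <- "load"
    contexts <- config$contexts %||% read_context_fasta(config$context_fasta)
    if (!length(contexts)) stop("no contexts to analyse")
    groups <- vapply(contexts, `[[`, "", "group")
    logline <- c(logline, sprintf("load: %d contexts (%s)",
                                  length(contexts),
                                  paste(sprintf("%s=%d",
                                                names(table(groups)),
                                                table(groups)),
                                        collapse = ", ")))

    stage <- "features"
    features <- exon_feature_table(contexts, config)
    f_path <- file.path(outdir, "features.tsv")
    .write_tsv(features, f_path); written <- c(written, f_path)
    logline <- c(logline, sprintf("features: %d rows", nrow(features)))

    stage <- "composition"
    by_group <- split(contexts, groups)
    comp_df <- do.call(rbind, lapply(names(by_group), function(g)
      .composition_df(positional_composition(by_group[[g]], "acceptor"),
                      g)))
    c_path <- file.path(outdir, "composition.tsv")
    .write_tsv(comp_df, c_path); written <- c(written, c_path)
    logline <- c(logline, "composition: acceptor frame, per group")

    stage <- "pu_profiles"
    acc_pos <- signed_positions(config$acceptor_range[1],
                                config$acceptor_range[2])
    don_pos <- signed_positions(config$donor_range[1],
                                config$donor_range[2])
    pu_tracks <- list(); prof_rows <- list()
    for (g in names(by_group)) {
      m_acc <- .pu_matrix(by_group[[g]], "acceptor", acc_pos, config$model)
      m_don <- .pu_matrix(by_group[[g]], "donor", don_pos, config$model)
      pu_tracks[[g]] <- m_acc
      prof_rows[[length(prof_rows) + 1L]] <-
        .profile_df(.profile_from_matrix(m_acc, "acceptor", acc_pos), g,
                    "real")
      prof_rows[[length(prof_rows) + 1L]] <-
        .profile_df(.profile_from_matrix(m_don, "donor", don_pos), g,
                    "real")
    }
    logline <- c(logline, "pu_profiles: real profiles done")

    stage <- "shuffled_background"
    for (g in names(by_group)) {
      ctxs <- by_group[[g]]
      if (!is.null(config$bg_exons) && length(ctxs) > config$bg_exons)
        ctxs <- ctxs[sort(sample.int(length(ctxs), config$bg_exons))]
      sh <- unlist(lapply(ctxs, masked_flank_shuffle,
                          n = config$bg_shuffles),
                   recursive = FALSE)
      m_acc <- .pu_matrix(sh, "acceptor", acc_pos, config$model)
      m_don <- .pu_matrix(sh, "donor", don_pos, config$model)
      prof_rows[[length(prof_rows) + 1L]] <-
        .profile_df(.profile_from_matrix(m_acc, "acceptor", acc_pos), g,
                    "shuffled")
      prof_rows[[length(prof_rows) + 1L]] <-
        .profile_df(.profile_from_matrix(m_don, "donor", don_pos), g,
                    "shuffled")
      logline <- c(logline,
                   sprintf("shuffled_background: %s, %d exons x %d shuffles",
                           g, length(ctxs), config$bg_shuffles))
    }
    p_path <- file.path(outdir, "pu_profile.tsv")
    .write_tsv(do.call(rbind, prof_rows), p_path)
    written <- c(written, p_path)

    stage <- "kmers"
    kmer_df <- NULL
    if (all(c("activated", "control") %in% names(by_group))) {
      kmer_df <- kmer_enrichment(by_group$activated, by_group$control,
                                 k = config$kmer_k, frame = "acceptor",
                                 range = config$kmer_range)
      k_path <- file.path(outdir, "kmers.tsv")
      .write_tsv(kmer_df, k_path); written <- c(written, k_path)
      logline <- c(logline, sprintf("kmers: k=%d, %d tested",
                                    config$kmer_k, nrow(kmer_df)))
    } else {
      logline <- c(logline, "kmers: skipped (need activated and control)")
    }

    stage <- "statistics"
    stats <- compare_groups(features, config, pu_tracks = pu_tracks)
    s_path <- file.path(outdir, "stats.json")
    jsonlite::write_json(stats, s_path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, na = "null")
    written <- c(written, s_path)

    stage <- "provenance"
    # hash the scientific parameters only: run-local paths (outdir,
    # input file names) must not break identity of identical analyses
    cfg_desc <- unclass(config)
    cfg_desc$outdir <- NULL
    cfg_desc$context_fasta <- NULL
    cfg_desc$contexts <- sprintf("%d contexts (inline)",
                                 length(config$contexts %||% list()))
    cfg_desc$model <- list(pair_energies = config$model$pair_energies,
                           stack_bonus = config$model$stack_bonus,
                           min_hairpin_loop = config$model$min_hairpin_loop,
                           kT = config$model$kT)
    cfg_json <- jsonlite::toJSON(cfg_desc, auto_unbox = TRUE, digits = 10)
    tmp <- file.path(outdir, ".config.json")
    con <- file(tmp, "wb"); writeLines(as.character(cfg_json), con, sep = "\n")
    close(con)
    cfg_hash <- unname(tools::md5sum(tmp))
    file.remove(tmp)
    prov <- list(package = "acceptorscape",
                 version = as.character(packageVersion("acceptorscape")),
                 seed = config$seed, config_md5 = cfg_hash,
                 n_contexts = length(contexts))
    pv_path <- file.path(outdir, "provenance.json")
    jsonlite::write_json(prov, pv_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, pv_path)

    stage <- "log"
    l_path <- file.path(outdir, "run.log")
    con <- file(l_path, "wb")
    writeLines(c("acceptorscape run_profile", logline, "done"), con,
               sep = "\n")
    close(con)
    invisible(stats)
  }, error = on_fail)
}
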