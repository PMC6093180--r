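#' Folding energy model
#'
#' A deliberately small nearest-neighbour model for the Boltzmann
#' ensemble of nested secondary structures: one energy per canonical
#' pair type (Watson-Crick plus GU wobble), a stacking bonus added when
#' two pairs are immediately nested (keyed by the outer pair), a minimum
#' hairpin-loop size, and the thermal energy kT.  PU values computed
#' under this model are meaningful for comparisons *within* a run
#' (group versus group, real versus shuffled); the model does not aim to
#' reproduce full Turner-parameter free energies, and an external
#' folding engine can be plugged in wherever a `(sequence, span) -> PU`
#' function is accepted.
#'
#' @param pair_energies named numeric, kcal/mol, for AU, UA, GC, CG, GU,
#'   UG; all must be <= 0.
#' @param stack_bonus scalar or named 6-vector (same names), kcal/mol,
#'   added when the outer pair of a stack has that type.
#' @param min_hairpin_loop minimum number of unpaired bases enclosed by
#'   a pair (>= 3).
#' @param kT thermal energy in kcal/mol; the default 0.6156 corresponds
#'   to 37 degrees C.
#' @return object of class `energy_model`.
#' @export
energy_model <- function(pair_energies = c(AU = -2, UA = -2, GC = -3,
                                           CG = -3, GU = -1, UG = -1),
                         stack_bonus = -1, min_hairpin_loop = 3L,
                         kT = 0.6156) {
  ptypes <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (!all(ptypes %in% names(pair_energies)))
    stop("pair_energies must name all of ", paste(ptypes, collapse = ", "))
  pair_energies <- pair_energies[ptypes]
  if (any(pair_energies > 0)) stop("pair energies must be <= 0")
  if (length(stack_bonus) == 1L && is.null(names(stack_bonus)))
    stack_bonus <- setNames(rep(stack_bonus, 6), ptypes)
  if (!all(ptypes %in% names(stack_bonus)))
    stop("stack_bonus must be a scalar or named over all pair types")
  stack_bonus <- stack_bonus[ptypes]
  if (min_hairpin_loop < 3) stop("min_hairpin_loop must be >= 3")
  if (kT <= 0) stop("kT must be positive")
  pairw <- matrix(0, 4, 4, dimnames = list(RNA_LETTERS, RNA_LETTERS))
  sigma <- matrix(1, 4, 4, dimnames = list(RNA_LETTERS, RNA_LETTERS))
  for (pt in ptypes) {
    a <- substr(pt, 1, 1); b <- substr(pt, 2, 2)
    pairw[a, b] <- exp(-pair_energies[[pt]] / kT)
    sigma[a, b] <- exp(-stack_bonus[[pt]] / kT)
  }
  structure(list(pair_energies = pair_energies, stack_bonus = stack_bonus,
                 min_hairpin_loop = as.integer(min_hairpin_loop), kT = kT,
                 pairw = pairw, sigma = sigma),
            class = "energy_model")
}

.check_model <- function(model) {
  if (!inherits(model, "energy_model"))
    stop("model must be created by energy_model()")
  model
}

#' Boltzmann partition function and base-pair probabilities
#'
#' Computes the total partition function Z (log domain), the symmetric
#' base-pair probability matrix and per-base unpaired probabilities over
#' all nested secondary structures of `seq`, by inside-outside
#' (McCaskill-style) recursions under the package [energy_model()].  The
#' empty structure carries weight 1, so Z >= 1.  Positions listed in
#' `forced_unpaired` are excluded from pairing, which is how constrained
#' partition functions for PU values are obtained.
#'
#' @param seq RNA string (A/C/G/U; N allowed with `permissive_n` and
#'   treated as unpairable).
#' @param model an [energy_model()].
#' @param forced_unpaired integer vector of 1-based positions that must
#'   stay unpaired, or `NULL`.
#' @param permissive_n allow N letters (unpairable) instead of erroring.
#' @return object of class `PartitionResult`: list with `logZ`, `Z`
#'   (may overflow to `Inf` for long sequences; `logZ` is exact),
#'   `pair_prob`, `unpaired_prob`.
#' @export
partition_function <- function(seq, model = energy_model(),
                               forced_unpaired = NULL,
                               permissive_n = FALSE) {
  .check_model(model)
  code <- .encode_rna(seq, allow_n = permissive_n)
  if (length(code) < 1) stop("sequence must have length >= 1")
  res <- .pf_run(code, model$pairw, model$sigma, model$min_hairpin_loop,
                 as.integer(forced_unpaired %||% integer()), TRUE)
  structure(list(logZ = res$logZ, Z = exp(res$logZ),
                 pair_prob = res$pair_prob,
                 unpaired_prob = res$unpaired_prob,
                 n = length(code)),
            class = "PartitionResult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probability that a span is entirely unpaired
#'
#' PU of positions `span[1]..span[2]` (1-based, inclusive) of `seq`:
#' the ratio of the partition function constrained to leave the span
#' unpaired to the unconstrained partition function.  PU of a span never
#' exceeds the PU of any of its sub-spans.
#'
#' @inheritParams partition_function
#' @param span integer length-2, `1 <= span[1] <= span[2] <= nchar(seq)`.
#' @return numeric in `[0, 1]`.
#' @export
unpaired_probability <- function(seq, span, model = energy_model(),
                                 permissive_n = FALSE) {
  .check_model(model)
  code <- .encode_rna(seq, allow_n = permissive_n)
  if (length(span) != 2 || span[1] > span[2] || span[1] < 1 ||
      span[2] > length(code))
    stop("invalid span: must satisfy 1 <= i <= j <= length(seq)")
  .pf_pu_span(code, as.integer(span[1]), as.integer(span[2]),
              model$pairw, model$sigma, model$min_hairpin_loop)
}

#' Pentamer PU at one position
#'
#' The probability that the pentamer centred at `center` is unpaired,
#' computed within three symmetric sequence contexts of
#' `context_lengths` nt on each side of the pentamer (substrings are
#' truncated at the sequence ends), and their arithmetic mean, which is
#' the value assigned to the middle pentamer position in positional
#' profiles.
#'
#' @inheritParams partition_function
#' @param center 1-based index of the pentamer middle; the pentamer
#'   `center-2 .. center+2` must lie inside the sequence.
#' @param context_lengths context sizes in nt (default 10/20/30).
#' @return object of class `PentamerPU`: list with `center`,
#'   `pu_by_context` (named numeric) and `pu_mean`.
#' @export
pentamer_pu <- function(seq, center, model = energy_model(),
                        context_lengths = c(10L, 20L, 30L),
                        permissive_n = FALSE) {
  .check_model(model)
  code <- .encode_rna(seq, allow_n = permissive_n)
  if (center - 2 < 1 || center + 2 > length(code))
    stop("pentamer not fully inside sequence")
  m <- .pf_pentamer_batch(code, as.integer(center), model$pairw,
                          model$sigma, model$min_hairpin_loop,
                          as.integer(context_lengths))
  pu <- setNames(as.numeric(m[1, ]), paste0("L", context_lengths))
  structure(list(center = center, pu_by_context = pu, pu_mean = mean(pu)),
            class = "PentamerPU")
}

# pentamer pu_mean for all valid signed positions of one context;
# returns numeric named by signed position (NA where pentamer does not fit)
.context_position_pu <- function(context, frame, positions,
                                 model, context_lengths = c(10L, 20L, 30L)) {
  seq <- .context_seq(context)
  code <- .encode_rna(seq, allow_n = TRUE)
  idx <- .signed_to_index(context, frame, positions)
  ok <- !is.na(idx) & idx - 2L >= 1L & idx + 2L <= length(code)
  out <- setNames(rep(NA_real_, length(positions)), positions)
  if (any(ok)) {
    m <- .pf_pentamer_batch(code, idx[ok], model$pairw, model$sigma,
                            model$min_hairpin_loop,
                            as.integer(context_lengths))
    out[ok] <- rowMeans(m)
  }
  out
}

#' Positional PU profile over a set of contexts
#'
#' Mean pentamer PU per signed position, in the acceptor frame (default
#' positions -100..+10) or donor frame (-10..+100).  Contexts too short
#' to populate a position simply contribute to fewer positions; the
#' per-position contribution counts are returned.
#'
#' @param contexts list of `SplicedContext`.
#' @param frame `"acceptor"` or `"donor"`.
#' @param model an [energy_model()].
#' @param positions signed positions (no 0); defaults to the frame's
#'   standard range.
#' @return object of class `PUProfile`: list with `frame`, `positions`,
#'   `mean_pu`, `n_per_position`.
#' @export
positional_pu_profile <- function(contexts, frame = c("acceptor", "donor"),
                                  model = energy_model(),
                                  positions = NULL) {
  frame <- match.arg(frame)
  if (!length(contexts)) stop("empty context list")
  if (is.null(positions))
    positions <- if (frame == "acceptor") signed_positions(-100, 10)
                 else signed_positions(-10, 100)
  sums <- setNames(numeric(length(positions)), positions)
  ns <- setNames(integer(length(positions)), positions)
  for (ctx in contexts) {
    pu <- .context_position_pu(ctx, frame, positions, model)
    ok <- !is.na(pu)
    sums[ok] <- sums[ok] + pu[ok]
    ns[ok] <- ns[ok] + 1L
  }
  mean_pu <- ifelse(ns > 0, sums / ns, NA_real_)
  structure(list(frame = frame, positions = positions,
                 mean_pu = setNames(as.numeric(mean_pu), positions),
                 n_per_position = ns),
            class = "PUProfile")
}

#' @export
print.PUProfile <- function(x, ...) {
  cat(sprintf("PUProfile [%s] %d positions (%d..%d), n up to %d\n",
              x$frame, length(x$positions), min(x$positions),
              max(x$positions), max(x$n_per_position)))
  invisible(x)
}

#' Mean flank PU of a single exon
#'
#' Mean of the per-position pentamer PU means over an inclusive signed
#' range of one context (e.g. acceptor -18..-40, a typical human
#' branch-point location, or the flank summaries -4..-100 and +7..+100).
#' Positions whose pentamer does not fit in the available sequence are
#' dropped from the mean.
#'
#' @inheritParams positional_pu_profile
#' @param context one `SplicedContext`.
#' @param range signed length-2 interval (any order, 0 skipped).
#' @return scalar PU mean.
#' @export
mean_flank_pu <- function(context, frame = c("acceptor", "donor"),
                          range, model = energy_model()) {
  frame <- match.arg(frame)
  positions <- signed_positions(range[1], range[2])
  pu <- .context_position_pu(context, frame, positions, model)
  if (all(is.na(pu)))
    stop("range outside the available sequence for exon ", context$exon_id)
  mean(pu, na.rm = TRUE)
}
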