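#' @title In-silico perturbation experiments
#' @name experiments
#' @description
#' Four study designs over a built model: (1) individual miRNA
#' over-expression with log2-ratio readout against the miRNA-free control;
#' (2) dose-response scans over a miRNA gene expression range; (3)
#' activation-threshold scans sweeping the receptor gene level under
#' constant ligand input; (4) an anti-miRNA screen in which each inhibitor
#' is applied alone against its over-expressed cognate miRNA and scored by
#' a paired two-sided t-test over the concentration changes of all model
#' components.
NULL

mirna_gene_ids <- function(model) {
  ids <- entity_ids(model)
  ids[vapply(model$entities, function(e) {
    e$role == "gene" && mirna_mat_id(e$id) %in% ids
  }, logical(1))]
}

## Steady state under clamp overrides, reusing one compiled network.
ss_clamped <- function(model, cmp, overrides, cfg) {
  if (length(overrides)) {
    idx <- match(names(overrides), cmp$ids)
    if (anyNA(idx))
      stop("unknown_participant: ",
           paste(names(overrides)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    for (i in seq_along(idx)) {
      at <- match(idx[i], cmp$clamp_idx)
      if (is.na(at)) {
        cmp$clamp_idx <- c(cmp$clamp_idx, idx[i])
        cmp$clamp_val <- c(cmp$clamp_val, overrides[[i]])
      } else cmp$clamp_val[at] <- overrides[[i]]
    }
  }
  init <- model$initial_marking[cmp$ids]
  simulate_model(cmp, n_steps = cfg$steps, cfg = cfg, record_every = 1e9,
                 init = init)$final
}

#' Baseline steady state of a model
#'
#' The control condition: ligand/metabolite clamps and configured gene
#' levels as built, no perturbation applied.
#'
#' @param model A `mirpetri_model`.
#' @param cfg A [kinetic_config()].
#' @return Named steady-state marking.
#' @export
control_state <- function(model, cfg = kinetic_config()) {
  steady_state(model, cfg = cfg)
}

#' Log2 ratios of two markings over a readout set
#'
#' Equal values (including two zeros) give exactly 0.
#'
#' @param state,control Named markings.
#' @param readouts Entity ids to compare.
#' @return Named numeric vector of log2(state/control).
#' @export
log2_ratio <- function(state, control, readouts = names(control)) {
  s <- state[readouts]; c0 <- control[readouts]
  r <- ifelse(s == c0, 0, log2(s / c0))
  stats::setNames(as.numeric(r), readouts)
}

#' Mask a log2-ratio matrix of negligible changes
#'
#' Entries with `|log2 ratio| < mask_threshold` are flagged (to be shown
#' in white), not dropped.
#'
#' @param values Numeric matrix (or vector) of log2 ratios.
#' @param mask_threshold Masking threshold in log2 units (default 0.001).
#' @return A list of class `mirpetri_heatmap` with `values` and logical
#'   `mask`.
#' @export
heatmap_result <- function(values, mask_threshold = 0.001) {
  structure(list(values = values, mask = abs(values) < mask_threshold,
                 mask_threshold = mask_threshold),
            class = "mirpetri_heatmap")
}

#' Individual miRNA over-expression experiment
#'
#' The control is the model with every miRNA gene silenced; the perturbed
#' state over-expresses one miRNA gene alone (expression of all other
#' miRNAs omitted). Repression of a target appears as a negative log2
#' ratio.
#'
#' @param model A `mirpetri_model`.
#' @param mirna miRNA id (its gene place).
#' @param level Gene expression level in nM.
#' @param readouts Readout ids (default: all cytoplasmic transcripts).
#' @param cfg A [kinetic_config()].
#' @return Named vector of log2(perturbed/control) over the readouts.
#' @export
overexpression_experiment <- function(model, mirna, level,
                                      readouts = NULL,
                                      cfg = kinetic_config()) {
  mgenes <- mirna_gene_ids(model)
  if (!mirna %in% mgenes)
    stop("unknown_participant: ", mirna, " is not a miRNA gene",
         call. = FALSE)
  if (is.null(readouts)) {
    readouts <- vapply(model$entities, function(e)
      if (e$role == "mRNA" && e$compartment == "cytoplasm") e$id else "",
      character(1))
    readouts <- readouts[nzchar(readouts)]
  }
  cmp <- compile_network(model, cfg)
  off <- stats::setNames(rep(0, length(mgenes)), mgenes)
  ctrl <- ss_clamped(model, cmp, off, cfg)
  pert <- off; pert[mirna] <- level
  st <- ss_clamped(model, cmp, pert, cfg)
  log2_ratio(st, ctrl, readouts)
}

#' Dose-response scan over a perturbed species
#'
#' Runs one steady state per level of a clamped species (a miRNA gene for
#' over-expression scans, an anti-miRNA pseudo-object for inhibitor
#' scans); all other miRNA genes are silenced unless listed in `keep`.
#'
#' @param model A `mirpetri_model`.
#' @param entity Clamped species id to scan.
#' @param levels Numeric vector of levels (nM), at least 2.
#' @param readouts Readout ids.
#' @param keep Named numeric of additional clamp overrides held fixed
#'   across the scan (e.g. a co-over-expressed miRNA gene).
#' @param cfg A [kinetic_config()].
#' @return A data frame with column `level` and one column per readout.
#' @export
dose_scan <- function(model, entity, levels, readouts,
                      keep = numeric(0), cfg = kinetic_config()) {
  stopifnot(length(levels) >= 2)
  mgenes <- mirna_gene_ids(model)
  cmp <- compile_network(model, cfg)
  base <- stats::setNames(rep(0, length(mgenes)), mgenes)
  base[names(keep)] <- keep
  rows <- lapply(levels, function(lv) {
    ov <- base; ov[entity] <- lv
    st <- ss_clamped(model, cmp, ov, cfg)
    c(level = lv, st[readouts])
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("level", readouts)
  df
}

#' Activation threshold of a driver gene
#'
#' Sweeps the driver gene expression level upward and returns the smallest
#' level at which every readout exceeds the activation criterion at steady
#' state; `Inf` is the sentinel when the criterion is never met.
#'
#' @param model A `mirpetri_model`.
#' @param driver_gene Gene id to sweep (e.g. the receptor gene).
#' @param levels Strictly increasing levels (nM).
#' @param readouts Readout ids that must all be active.
#' @param criterion `"epsilon"` (steady state > `epsilon`) or
#'   `"fraction"` (> `fraction` of the readout's steady state at the top
#'   level of the same scan).
#' @param epsilon Absolute activation level (nM).
#' @param fraction Fraction of maximum for the alternative criterion.
#' @param keep Named numeric of clamp overrides held fixed (e.g. a miRNA
#'   gene level).
#' @param cfg A [kinetic_config()].
#' @return The threshold level, or `Inf`.
#' @export
activation_threshold <- function(model, driver_gene, levels, readouts,
                                 criterion = c("epsilon", "fraction"),
                                 epsilon = NULL, fraction = 0.1,
                                 keep = numeric(0),
                                 cfg = kinetic_config()) {
  criterion <- match.arg(criterion)
  stopifnot(length(levels) >= 1, !is.unsorted(levels, strictly = TRUE))
  if (is.null(epsilon)) epsilon <- cfg$activation_epsilon
  mgenes <- mirna_gene_ids(model)
  cmp <- compile_network(model, cfg)
  base <- stats::setNames(rep(0, length(mgenes)), mgenes)
  base[names(keep)] <- keep
  states <- lapply(levels, function(lv) {
    ov <- base; ov[driver_gene] <- lv
    ss_clamped(model, cmp, ov, cfg)[readouts]
  })
  thr <- if (criterion == "epsilon") rep(epsilon, length(readouts))
         else fraction * states[[length(states)]]
  for (i in seq_along(levels))
    if (all(states[[i]] > thr)) return(levels[i])
  Inf
}

#' Paired two-sided t-test p-value between two markings
#'
#' The significance of the concentration changes of all matched model
#' components between a perturbed state and its control. Identical
#' markings give p = 1 by convention; a uniform nonzero shift with zero
#' dispersion gives the smallest representable p.
#'
#' @param state,control Named markings over the same component set.
#' @param variant `"paired"` (default) or `"welch"` (unpaired
#'   unequal-variance).
#' @return p-value in (0, 1].
#' @export
t_test_p_value <- function(state, control, variant = c("paired", "welch")) {
  variant <- match.arg(variant)
  if (!setequal(names(state), names(control)))
    stop("component sets differ", call. = FALSE)
  x <- as.numeric(state[names(control)])
  y <- as.numeric(control)
  n <- length(x)
  if (n < 2) stop("need >= 2 components", call. = FALSE)
  if (variant == "paired") {
    d <- x - y
    if (all(d == 0)) return(1)
    s <- stats::sd(d)
    if (s == 0) return(.Machine$double.xmin)
    tstat <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  } else {
    if (all(x == y) && stats::sd(x) == stats::sd(y) &&
        isTRUE(all.equal(x, y))) return(1)
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx + vy == 0) return(if (mean(x) == mean(y)) 1
                             else .Machine$double.xmin)
    se2 <- vx / n + vy / n
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }
  max(p, .Machine$double.xmin)
}

#' Screen anti-miRNA inhibitors one at a time
#'
#' For each miRNA, its gene is over-expressed alone (`overexpress_level`)
#' and its inhibitor pseudo-object is clamped at each dose. Per dose the
#' end-state marking and the log2 heatmap row against the
#' miRNA-over-expressed control are recorded; the per-inhibitor p-value is
#' the paired t-test over all model components at the top dose.
#'
#' @param model A `mirpetri_model` built `with_anti_mirnas = TRUE`.
#' @param anti_ids miRNA ids to screen (default: all).
#' @param dose_levels Anti-miRNA doses in nM (default 0 and the
#'   saturating dose, 100 x the over-expression level).
#' @param readouts Heatmap readout ids (default: active/phosphorylated
#'   proteins).
#' @param overexpress_level miRNA gene over-expression level (nM).
#' @param cfg A [kinetic_config()].
#' @return A list of class `mirpetri_screen`: `per_anti` (per-miRNA list
#'   with states, control and `p_value`), `heatmap` (a
#'   [heatmap_result()] of top-dose log2 ratios, inhibitors x readouts),
#'   `dose_levels`, `overexpress_level`.
#' @export
anti_mirna_screen <- function(model, anti_ids = NULL, dose_levels = NULL,
                              readouts = NULL, overexpress_level = 1,
                              cfg = kinetic_config()) {
  mgenes <- mirna_gene_ids(model)
  if (is.null(anti_ids)) anti_ids <- mgenes
  stopifnot(all(anti_ids %in% mgenes))
  missing_anti <- setdiff(anti_id(anti_ids), entity_ids(model))
  if (length(missing_anti))
    stop("unknown_participant: ", paste(missing_anti, collapse = ", "),
         " (build the model with_anti_mirnas = TRUE)", call. = FALSE)
  if (is.null(dose_levels))
    dose_levels <- c(0, 100 * overexpress_level)
  if (is.null(readouts)) {
    readouts <- vapply(model$entities, function(e)
      if (e$role == "protein" &&
          grepl("^(P|Active)-", e$id)) e$id else "", character(1))
    readouts <- readouts[nzchar(readouts)]
  }
  cmp <- compile_network(model, cfg)
  off <- stats::setNames(rep(0, length(mgenes)), mgenes)
  per_anti <- list()
  top_rows <- list()
  for (m in anti_ids) {
    ov <- off; ov[m] <- overexpress_level
    ctrl <- ss_clamped(model, cmp, ov, cfg)
    states <- lapply(dose_levels, function(d) {
      ovd <- ov; ovd[anti_id(m)] <- d
      ss_clamped(model, cmp, ovd, cfg)
    })
    names(states) <- as.character(dose_levels)
    top <- states[[length(states)]]
    per_anti[[m]] <- list(
      mirna = m, control = ctrl, states = states,
      p_value = t_test_p_value(top, ctrl))
    top_rows[[m]] <- log2_ratio(top, ctrl, readouts)
  }
  hm <- do.call(rbind, top_rows)
  structure(list(per_anti = per_anti,
                 heatmap = heatmap_result(hm),
                 dose_levels = dose_levels,
                 overexpress_level = overexpress_level,
                 readouts = readouts),
            class = "mirpetri_screen")
}

#' Rank screened anti-miRNAs by p-value
#'
#' Ascending by raw p-value with lexicographic tie-breaking; rows below
#' `alpha` are flagged as the top set. A Benjamini-Hochberg adjusted
#' column is reported alongside but does not drive the ranking.
#'
#' @param screen A `mirpetri_screen`.
#' @param alpha Significance cut-off (default 0.05).
#' @return A data frame with columns `anti_mirna`, `p_value`, `p_bh`,
#'   `top`.
#' @export
rank_anti_mirnas <- function(screen, alpha = 0.05) {
  if (!length(screen$per_anti))
    return(data.frame(anti_mirna = character(0), p_value = numeric(0),
                      p_bh = numeric(0), top = logical(0)))
  ids <- names(screen$per_anti)
  p <- vapply(screen$per_anti, function(x) x$p_value, numeric(1))
  ord <- order(p, ids)
  df <- data.frame(anti_mirna = paste0("anti-", ids[ord]),
                   p_value = unname(p[ord]),
                   p_bh = stats::p.adjust(p, "BH")[ord],
                   top = unname(p[ord]) < alpha,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Per-miRNA and per-target interaction counts
#'
#' @param table A `mirpetri_targets` table.
#' @param mirnas Optional miRNA ids to restrict/order the per-miRNA counts
#'   (absent ids count 0).
#' @return A list with `per_mirna` (distinct targets per miRNA) and
#'   `per_target` (distinct miRNAs per target).
#' @export
target_count_histogram <- function(table, mirnas = NULL) {
  uniq <- unique(table[c("mirna", "target")])
  per_mirna <- vapply(split(uniq$target, uniq$mirna),
                      function(x) length(unique(x)), integer(1))
  per_target <- vapply(split(uniq$mirna, uniq$target),
                       function(x) length(unique(x)), integer(1))
  if (!is.null(mirnas)) {
    out <- stats::setNames(integer(length(mirnas)), mirnas)
    hit <- intersect(mirnas, names(per_mirna))
    out[hit] <- per_mirna[hit]
    per_mirna <- out
  }
  list(per_mirna = per_mirna, per_target = per_target)
}
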