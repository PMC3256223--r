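#' @title Discrete-time hybrid Petri-net engine
#' @name engine
#' @description
#' Each simulation step evaluates every transition against the step's
#' starting marking (synchronous update): a mass-action-style flux is
#' computed from substrate and enzyme concentrations and damped by bound
#' inhibitors; fluxes are truncated proportionally where a place cannot
#' cover the total demand, so no concentration ever goes negative and the
#' update is order-independent. After firing, a multi-timescale decay
#' policy removes a fixed fraction of proteins and compounds every step and
#' of ligand-receptor complexes every tenth step; the decayed amount is
#' computed on the step's starting concentration for pre-existing species
#' and on the post-fire concentration for species first created in the
#' step. Clamped species are then reset to their clamp values.
NULL

resolve_k <- function(reaction, cfg) {
  if (!is.na(reaction$k)) return(reaction$k)
  kc <- reaction$kclass %||% reaction$rtype
  k <- cfg$k_default[[kc]]
  if (is.null(k)) k <- cfg$k_default[["other"]]
  k
}

arc_split <- function(reaction) {
  a <- reaction$arcs
  list(sub = a[a$role == "substrate", , drop = FALSE],
       prod = a[a$role == "product", , drop = FALSE],
       enz = a[a$role == "enzyme", , drop = FALSE],
       inh = a[a$role == "inhibitor", , drop = FALSE])
}

#' Transition flux of a single reaction
#'
#' Default rate law: `k * prod(substrate^w) * prod(enzyme^w) /
#' (1 + inhibitory_parameter * sum(w * inhibitor))`. The flux is zero
#' whenever any substrate or enzyme is absent, also for reactions carrying
#' an explicit flux override.
#'
#' @param reaction A reaction from a `mirpetri_model`.
#' @param m Named marking vector (nM).
#' @param cfg A [kinetic_config()].
#' @return Non-negative flux in nM/step.
#' @export
transition_flux <- function(reaction, m, cfg = kinetic_config()) {
  p <- arc_split(reaction)
  need <- c(p$sub$place, p$enz$place, p$inh$place)
  if (any(!need %in% names(m)))
    stop("missing_place: ", paste(setdiff(need, names(m)), collapse = ", "),
         call. = FALSE)
  gate <- c(p$sub$place, p$enz$place)
  if (length(gate) && any(m[gate] <= 0)) return(0)
  if (!is.na(reaction$flux_override)) return(reaction$flux_override)
  k <- resolve_k(reaction, cfg)
  f <- k
  if (nrow(p$sub)) f <- f * prod(m[p$sub$place] ^ p$sub$weight)
  if (nrow(p$enz)) f <- f * prod(m[p$enz$place] ^ p$enz$weight)
  if (nrow(p$inh))
    f <- f / (1 + cfg$inhibitory_parameter * sum(p$inh$weight * m[p$inh$place]))
  f
}

reverse_flux <- function(reaction, m, cfg) {
  p <- arc_split(reaction)
  gate <- c(p$prod$place, p$enz$place)
  if (length(gate) && any(m[gate] <= 0)) return(0)
  k <- resolve_k(reaction, cfg)
  f <- k
  if (nrow(p$prod)) f <- f * prod(m[p$prod$place] ^ p$prod$weight)
  if (nrow(p$enz)) f <- f * prod(m[p$enz$place] ^ p$enz$weight)
  if (nrow(p$inh))
    f <- f / (1 + cfg$inhibitory_parameter * sum(p$inh$weight * m[p$inh$place]))
  f
}

#' Firing state of a transition
#'
#' `"forward"` when the forward flux is positive (a marking below the
#' consumption limit truncates the flux rather than blocking the firing),
#' `"backward"` for reversible transitions whose mirrored (product-side)
#' flux is positive while the forward flux is zero, else `"inactive"`.
#'
#' @inheritParams transition_flux
#' @return One of `"forward"`, `"backward"`, `"inactive"`.
#' @export
firing_state <- function(reaction, m, cfg = kinetic_config()) {
  if (transition_flux(reaction, m, cfg) > 0) return("forward")
  if (isTRUE(reaction$reversible) && reverse_flux(reaction, m, cfg) > 0)
    return("backward")
  "inactive"
}

#' Fire a single transition
#'
#' Moves `weight * flux` along every mass-moving arc; with the
#' worked-example convention (`cfg$consume_enzyme = TRUE`) enzyme arcs are
#' consumed like substrates. Flux is truncated so that no place goes
#' negative.
#'
#' @inheritParams transition_flux
#' @param flux Flux to apply (nM/step).
#' @return The post-fire marking.
#' @export
fire <- function(reaction, m, flux, cfg = kinetic_config()) {
  p <- arc_split(reaction)
  inp <- p$sub
  if (isTRUE(cfg$consume_enzyme) && nrow(p$enz)) inp <- rbind(inp, p$enz)
  if (nrow(inp)) {
    lim <- min(m[inp$place] / inp$weight)
    flux <- min(flux, lim)
  }
  flux <- max(flux, 0)
  if (nrow(inp)) m[inp$place] <- m[inp$place] - inp$weight * flux
  if (nrow(p$prod)) m[p$prod$place] <- m[p$prod$place] + p$prod$weight * flux
  pmax(m, 0)
}

#' Build the decay policy for a model
#'
#' Proteins and compounds follow the fast timescale (default rate 0.09,
#' every step); complexes tagged `"ligand_receptor"` follow the slow
#' timescale (default rate 0.2, every 10 steps); genes, transcripts, mature
#' miRNAs, other complexes and pseudo-objects decay only through their
#' explicit decay reactions.
#'
#' @param model A `mirpetri_model`.
#' @param cfg A [kinetic_config()].
#' @return A list with named `rate` and `period` vectors over all places.
#' @export
decay_policy <- function(model, cfg = kinetic_config()) {
  ids <- entity_ids(model)
  rate <- stats::setNames(numeric(length(ids)), ids)
  period <- stats::setNames(rep(1L, length(ids)), ids)
  for (e in model$entities) {
    if (e$role %in% c("protein", "compound")) {
      rate[e$id] <- cfg$decay_protein_rate
      period[e$id] <- cfg$decay_protein_period
    } else if (e$role == "complex" && "ligand_receptor" %in% e$tags) {
      rate[e$id] <- cfg$decay_ligand_receptor_rate
      period[e$id] <- cfg$decay_ligand_receptor_period
    }
  }
  list(rate = rate, period = period)
}

#' Apply one round of policy decay to a marking
#'
#' Each due species loses `rate * base`, where the base is the
#' start-of-step concentration (`m_start`) for species that already
#' existed, and the current (post-fire) concentration for species created
#' during the step.
#'
#' @param m Post-fire marking.
#' @param step_index 1-based step counter; a class is due when
#'   `step_index %% period == 0`.
#' @param policy A [decay_policy()].
#' @param m_start Start-of-step marking (defaults to `m`).
#' @return The decayed marking (floored at 0).
#' @export
apply_decay <- function(m, step_index, policy, m_start = m) {
  due <- (step_index %% policy$period) == 0
  base <- ifelse(m_start > 0, m_start, m)
  pmax(m - ifelse(due, policy$rate * base, 0), 0)
}

## --- compiled fast path -------------------------------------------------

#' Compile a model into matrix form for simulation
#'
#' @param model A `mirpetri_model`.
#' @param cfg A [kinetic_config()].
#' @return An opaque compiled-network list used by [step_marking()] and
#'   [simulate_model()].
#' @export
compile_network <- function(model, cfg = kinetic_config()) {
  ids <- entity_ids(model)
  np <- length(ids); nr <- length(model$reactions)
  idx <- stats::setNames(seq_len(np), ids)
  W_sub <- matrix(0, np, nr); W_enz <- matrix(0, np, nr)
  W_inh <- matrix(0, np, nr); W_out <- matrix(0, np, nr)
  k <- numeric(nr); override <- rep(NA_real_, nr)
  reversible <- logical(nr)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    k[j] <- resolve_k(r, cfg)
    override[j] <- r$flux_override
    reversible[j] <- isTRUE(r$reversible)
    for (i in seq_len(nrow(r$arcs))) {
      a <- r$arcs[i, ]
      pi <- idx[[a$place]]
      if (a$role == "substrate") W_sub[pi, j] <- W_sub[pi, j] + a$weight
      else if (a$role == "enzyme") W_enz[pi, j] <- W_enz[pi, j] + a$weight
      else if (a$role == "inhibitor") W_inh[pi, j] <- W_inh[pi, j] + a$weight
      else W_out[pi, j] <- W_out[pi, j] + a$weight
    }
  }
  W_move <- W_sub + if (isTRUE(cfg$consume_enzyme)) W_enz else 0
  W_se <- W_sub + W_enz
  draw_idx <- lapply(seq_len(nr), function(j) which(W_move[, j] > 0))
  policy <- decay_policy(model, cfg)
  clamp_idx <- idx[names(model$clamps)]
  list(ids = ids, np = np, nr = nr, k = k, override = override,
       reversible = reversible, W_sub = W_sub, W_enz = W_enz,
       W_inh = W_inh, W_out = W_out, W_move = W_move, W_se = W_se,
       W_se_pos = (W_se > 0) * 1, draw_idx = draw_idx,
       rate = policy$rate, period = policy$period,
       clamp_idx = clamp_idx, clamp_val = unname(model$clamps),
       any_inh = any(W_inh > 0), any_rev = any(reversible))
}

compiled_flux <- function(cmp, m, cfg) {
  logm <- ifelse(m > 0, log(m), 0)
  pr <- exp(as.vector(crossprod(cmp$W_se, logm)))
  zero <- as.vector(crossprod(cmp$W_se_pos, as.numeric(m <= 0))) > 0
  f <- cmp$k * pr
  if (cmp$any_inh) {
    denom <- 1 + cfg$inhibitory_parameter * as.vector(crossprod(cmp$W_inh, m))
    f <- f / denom
  }
  ov <- !is.na(cmp$override)
  f[ov] <- cmp$override[ov]
  f[zero] <- 0
  f
}

#' Advance a marking by one synchronous engine step
#'
#' @param cmp A [compile_network()] result.
#' @param m Marking vector aligned with `cmp$ids`.
#' @param step_index 1-based step counter (drives periodic decay).
#' @param cfg A [kinetic_config()].
#' @return The next marking.
#' @export
step_marking <- function(cmp, m, step_index, cfg = kinetic_config()) {
  f <- compiled_flux(cmp, m, cfg)
  demand <- as.vector(cmp$W_move %*% f)
  if (any(demand > m)) {
    r <- rep(1, cmp$np)
    pos <- demand > 0
    r[pos] <- pmin(1, m[pos] / demand[pos])
    scale <- vapply(seq_len(cmp$nr), function(j) {
      di <- cmp$draw_idx[[j]]
      if (length(di)) min(r[di]) else 1
    }, numeric(1))
    f <- f * scale
  }
  m1 <- m - as.vector(cmp$W_move %*% f) + as.vector(cmp$W_out %*% f)
  if (cmp$any_rev) {
    bwd <- cmp$reversible & f == 0
    if (any(bwd)) {
      for (j in which(bwd)) {
        sub <- cmp$W_sub[, j]; out <- cmp$W_out[, j]; enz <- cmp$W_enz[, j]
        gate <- which(out > 0 | enz > 0)
        if (all(m[gate] > 0)) {
          fb <- cmp$k[j] * prod(m[out > 0] ^ out[out > 0]) *
            (if (any(enz > 0)) prod(m[enz > 0] ^ enz[enz > 0]) else 1)
          lim <- min(m1[out > 0] / out[out > 0])
          fb <- min(fb, lim)
          m1 <- m1 - out * fb + sub * fb
        }
      }
    }
  }
  m1 <- pmax(m1, 0)
  due <- (step_index %% cmp$period) == 0
  base <- ifelse(m > 0, m, m1)
  m2 <- pmax(m1 - ifelse(due, cmp$rate * base, 0), 0)
  if (length(cmp$clamp_idx)) m2[cmp$clamp_idx] <- cmp$clamp_val
  m2
}

#' Simulate a model to (quasi-)steady state
#'
#' Runs the synchronous engine from the model's initial marking (clamps
#' imposed), recording the trajectory, and stops early once the maximum
#' absolute marking change in a step falls below `cfg$tol`.
#'
#' @param model A `mirpetri_model` (or a precompiled network from
#'   [compile_network()], in which case `init` must be supplied).
#' @param n_steps Step budget (default `cfg$steps`).
#' @param cfg A [kinetic_config()].
#' @param record_every Record every k-th step (step 0 and the final step
#'   are always recorded).
#' @param init Optional named initial marking overriding the model's.
#' @return A `mirpetri_trajectory`: list with `steps` (recorded indices),
#'   `marking` (matrix, rows = recorded steps), `final` (named vector),
#'   `steady` (logical), `n_steps_run`, and `meta`.
#' @export
simulate_model <- function(model, n_steps = NULL, cfg = kinetic_config(),
                           record_every = 1L, init = NULL) {
  if (inherits(model, "mirpetri_model")) {
    cmp <- compile_network(model, cfg)
    m <- model$initial_marking[cmp$ids]
  } else {
    cmp <- model
    if (is.null(init)) stop("init marking required for a compiled network")
    m <- init[cmp$ids]
  }
  if (!is.null(init)) {
    m[names(init)] <- init
  }
  names(m) <- cmp$ids
  if (length(cmp$clamp_idx)) m[cmp$clamp_idx] <- cmp$clamp_val
  if (is.null(n_steps)) n_steps <- cfg$steps
  stopifnot(n_steps >= 1)
  rec_steps <- 0L
  rec <- list(m)
  steady <- FALSE
  i <- 0L
  while (i < n_steps) {
    i <- i + 1L
    m_next <- step_marking(cmp, m, i, cfg)
    delta <- max(abs(m_next - m))
    m <- m_next
    if (i %% record_every == 0L || i == n_steps) {
      rec_steps <- c(rec_steps, i)
      rec[[length(rec) + 1L]] <- m
    }
    if (delta < cfg$tol) { steady <- TRUE; break }
  }
  if (rec_steps[length(rec_steps)] != i) {
    rec_steps <- c(rec_steps, i)
    rec[[length(rec) + 1L]] <- m
  }
  marking <- do.call(rbind, rec)
  colnames(marking) <- cmp$ids
  structure(list(steps = rec_steps, marking = marking,
                 final = stats::setNames(as.numeric(m), cmp$ids),
                 steady = steady, n_steps_run = i,
                 meta = list(clamps = stats::setNames(cmp$clamp_val,
                                                      cmp$ids[cmp$clamp_idx]),
                             tol = cfg$tol)),
            class = "mirpetri_trajectory")
}

#' Steady-state marking of a model
#'
#' @inheritParams simulate_model
#' @return Named numeric marking at the end of the run.
#' @export
steady_state <- function(model, cfg = kinetic_config(), n_steps = NULL,
                         init = NULL) {
  simulate_model(model, n_steps = n_steps, cfg = cfg,
                 record_every = 64L, init = init)$final
}

#' Export a trajectory as a wide TSV (step, one column per species)
#'
#' @param traj A `mirpetri_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(step = traj$steps, traj$marking, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
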