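#' Sampling design for captures and observations
#'
#' Captures and observations are both two-stage detections of grouping
#' events: an event in a sampled behavioural timestep is detected with
#' probability `pcg` (captures) or `pmg` (observations), and each individual
#' within a detected event is detected with probability `pci` / `pmi`.
#' Captures mark individuals; observations only register individuals that
#' are already marked. In a timestep listed for both, captures take
#' precedence (only the capture process runs).
#'
#' @param cap_ts Integer vector of behavioural timesteps with captures.
#' @param obs_ts Integer vector of behavioural timesteps with observations.
#' @param pcg,pci Capture event- and individual-detection probabilities.
#' @param pmg,pmi Observation event- and individual-detection
#'   probabilities.
#' @param pre_cap Ids of individuals marked before the study.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(cap_ts = integer(), obs_ts = integer(),
                            pcg = 1, pci = 1, pmg = 1, pmi = 1,
                            pre_cap = integer()) {
  probs <- c(pcg, pci, pmg, pmi)
  if (any(probs < 0 | probs > 1)) {
    stop("detection probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(cap_ts = as.integer(cap_ts), obs_ts = as.integer(obs_ts),
                 pcg = pcg, pci = pci, pmg = pmg, pmi = pmi,
                 pre_cap = as.integer(pre_cap)),
            class = "sampling_design")
}

#' Sample captures and observations from grouping events
#'
#' Simulates the observation process on a group-by-individual matrix.
#' Timesteps are processed in order; individuals captured at a timestep are
#' marked from that timestep onwards, and observation detections of
#' unmarked individuals are discarded.
#'
#' @param gbi A `gbi` object.
#' @param design A [sampling_design()] object; its timesteps must occur in
#'   the GBI.
#' @param seed Optional integer seed.
#' @return List of class `observation_result`: `captured` and `observed`
#'   binary matrices (same shape as `gbi$matrix`), `first_capture` (named
#'   by id, behavioural timestep of first capture, NA if never; pre-marked
#'   individuals get 0), `marked` (ids marked by the end), `ids`,
#'   `timestep`.
#' @export
cap_and_obs <- function(gbi, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- gbi$matrix
  ids <- gbi$ids
  cap <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  obs <- cap
  marked <- intersect(design$pre_cap, ids)
  first <- stats::setNames(rep(NA_real_, length(ids)), ids)
  first[as.character(marked)] <- 0
  for (ts in sort(unique(gbi$timestep))) {
    rows <- which(gbi$timestep == ts)
    if (ts %in% design$cap_ts) {
      pg <- design$pcg; pi_ <- design$pci; capture <- TRUE
    } else if (ts %in% design$obs_ts) {
      pg <- design$pmg; pi_ <- design$pmi; capture <- FALSE
    } else next
    det_ev <- rows[stats::runif(length(rows)) < pg]
    for (r in det_ev) {
      memb <- which(m[r, ] == 1L)
      det <- memb[stats::runif(length(memb)) < pi_]
      if (capture) {
        cap[r, det] <- 1L
        newly <- setdiff(ids[det], marked)
        if (length(newly)) {
          marked <- c(marked, newly)
          first[as.character(newly)] <- ts
        }
      } else {
        det <- det[ids[det] %in% marked]
        obs[r, det] <- 1L
      }
    }
  }
  structure(list(captured = cap, observed = obs, first_capture = first,
                 marked = marked, ids = ids, timestep = gbi$timestep),
            class = "observation_result")
}

#' Build capture histories from sampled grouping events
#'
#' Converts one or more [cap_and_obs()] results into behavioural- and
#' demographic-timestep capture-history matrices over a fixed set of
#' individuals. The behavioural entry is 1 iff the individual was captured
#' or observed in any event at that timestep; the demographic history is
#' the OR-reduction over each demographic step's behavioural timesteps.
#'
#' @param obs An `observation_result` or a list of them (e.g. one per
#'   demographic step).
#' @param demographic_map Integer vector mapping every behavioural timestep
#'   (by position: element `t` is the demographic step of behavioural
#'   timestep `t`) to a demographic step; must cover all timesteps present.
#' @param ids Master id vector fixing row order (defaults to the union of
#'   ids in `obs`).
#' @return List of class `capture_data`: `behavioural` (N x n behavioural
#'   timesteps), `demographic` (N x n demographic steps), `first_capture`
#'   (behavioural timestep of first capture per id; 0 = pre-marked, NA =
#'   never), `ids`.
#' @export
cap_dat_gen <- function(obs, demographic_map, ids = NULL) {
  if (inherits(obs, "observation_result")) obs <- list(obs)
  if (is.null(ids)) {
    ids <- sort(unique(unlist(lapply(obs, function(o) o$ids))))
  }
  n_beh <- length(demographic_map)
  beh <- matrix(0L, length(ids), n_beh,
                dimnames = list(ids, seq_len(n_beh)))
  first <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (o in obs) {
    if (any(!(o$timestep %in% seq_len(n_beh)))) {
      stop("behavioural timestep not covered by `demographic_map`",
           call. = FALSE)
    }
    det <- (o$captured + o$observed) > 0
    col <- match(o$ids, ids)
    for (r in seq_len(nrow(det))) {
      d <- which(det[r, ])
      if (length(d)) beh[col[d], o$timestep[r]] <- 1L
    }
    fc <- o$first_capture
    idx <- match(as.integer(names(fc)), ids)
    upd <- !is.na(fc) & (is.na(first[idx]) | fc < first[idx])
    first[idx[upd]] <- fc[upd]
  }
  steps <- sort(unique(demographic_map))
  dem <- sapply(steps, function(s) {
    as.integer(rowSums(beh[, demographic_map == s, drop = FALSE]) > 0)
  })
  dem <- matrix(dem, nrow = length(ids),
                dimnames = list(ids, steps))
  structure(list(behavioural = beh, demographic = dem,
                 first_capture = first, ids = ids),
            class = "capture_data")
}

#' Compare sampled, event-derived and underlying networks
#'
#' Runs the fidelity comparison of [check_interaction_network()] for a
#' sampled (observed) network against both the full event-derived network
#' and the underlying generative network. Non-detected individuals should
#' be included as zero rows so node sets match.
#'
#' @param sampled_net Network built from detected events/individuals.
#' @param event_net Network built from all grouping events.
#' @param underlying_net The generative network.
#' @param n_perm Permutations for the matrix regressions.
#' @param seed Optional integer seed.
#' @return List with `vs_event` and `vs_underlying`, each a
#'   `network_check`.
#' @export
obs_net_checker <- function(sampled_net, event_net, underlying_net,
                            n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(
    vs_event = check_interaction_network(sampled_net, event_net, n_perm),
    vs_underlying = check_interaction_network(sampled_net, underlying_net,
                                              n_perm)
  )
}

#' Write capture histories to CSV
#'
#' One row per individual with the demographic history columns, the
#' first-capture occasion, and a MARK-style `ch` string for
#' interoperability.
#'
#' @param capdat A `capture_data` object.
#' @param path File path.
#' @export
write_capture_history <- function(capdat, path) {
  dem <- capdat$demographic
  out <- data.frame(id = capdat$ids, dem, check.names = FALSE)
  names(out)[-1] <- paste0("occ_", colnames(dem))
  out$first_capture <- capdat$first_capture
  out$ch <- apply(dem, 1, paste0, collapse = "")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
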