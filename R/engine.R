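# Maximally parallel token-game engine.
#
# Semantics per discrete step:
#   * A transition is enabled when every input place holds at least
#     ceiling(weight) unreserved tokens (for integer weights this is the
#     classical rule; a fractional input arc needs 1 waiting token).
#   * The step's firing multiset is built by iterated uniform-random
#     reservation: among the transitions enabled against the residual
#     unreserved marking, one is drawn uniformly, its token demand for this
#     step is reserved and its count incremented; the loop ends when nothing
#     is enabled, which makes the multiset maximal by construction.
#   * Integer-weight arcs move `weight` tokens per firing. A fractional arc
#     w = p/q carries an exact credit: each firing adds p to an integer
#     numerator over q, and whole tokens move whenever the numerator reaches
#     q, so exactly p transfers happen in every q consecutive firing steps.
#     Any transition carrying a fractional arc (and any transition without
#     input arcs) fires at most once per step, keeping the credit well
#     defined.
#   * Productions become visible only at the step boundary: tokens produced
#     in step k are first consumable in step k+1.

ceil_div <- function(num, den) (num + den - 1L) %/% den

# Flatten a net into indexed structures for the hot loop. Zero-weight arcs
# are inert (no enabling requirement, no transfer) and are dropped here.
compile_net <- function(net) {
  pl <- net$places
  tr <- net$transitions
  nP <- length(pl)
  nT <- length(tr)
  a <- net$arcs[net$arcs$num > 0L, , drop = FALSE]
  frac <- (a$num %% a$den) != 0L
  fa <- a[frac, , drop = FALSE]
  frac_keys <- arc_key(fa$source, fa$target)

  req <- matrix(0L, nrow = nT, ncol = nP, dimnames = list(tr, pl))
  in_int <- out_int <- in_frac <- out_frac <- vector("list", nT)
  capped <- logical(nT)
  for (ti in seq_len(nT)) {
    t <- tr[ti]
    inn <- a[a$target == t, , drop = FALSE]
    out <- a[a$source == t, , drop = FALSE]
    ifr <- (inn$num %% inn$den) != 0L
    ofr <- (out$num %% out$den) != 0L
    ii <- inn[!ifr, , drop = FALSE]
    in_int[[ti]] <- list(idx = match(ii$source, pl), w = ii$num %/% ii$den)
    oo <- out[!ofr, , drop = FALSE]
    out_int[[ti]] <- list(idx = match(oo$target, pl), w = oo$num %/% oo$den)
    fi <- inn[ifr, , drop = FALSE]
    in_frac[[ti]] <- list(idx = match(fi$source, pl), num = fi$num,
                          den = fi$den,
                          fid = match(arc_key(fi$source, fi$target), frac_keys))
    fo <- out[ofr, , drop = FALSE]
    out_frac[[ti]] <- list(idx = match(fo$target, pl), num = fo$num,
                           den = fo$den,
                           fid = match(arc_key(fo$source, fo$target), frac_keys))
    if (nrow(inn)) {
      req[ti, match(inn$source, pl)] <- ceil_div(inn$num, inn$den)
    }
    capped[ti] <- any(ifr) || any(ofr) || nrow(inn) == 0L
  }

  list(places = pl, transitions = tr, nP = nP, nT = nT,
       req = req, in_int = in_int, out_int = out_int,
       in_frac = in_frac, out_frac = out_frac,
       capped = capped,
       frac_keys = frac_keys, frac_den = fa$den)
}

# Which transitions are enabled against `avail` (residual unreserved tokens),
# excluding once-per-step transitions that already fired.
enabled_mask <- function(cn, avail, used_cap) {
  ok <- .rowSums(cn$req > rep(avail, each = cn$nT), cn$nT, cn$nP) == 0L
  ok & !(cn$capped & used_cap)
}

# Tokens a single firing of transition ti will remove this step, given the
# start-of-step credit; fractional inputs consume only on transfer steps.
reserve_one <- function(cn, avail, credit, ti) {
  ii <- cn$in_int[[ti]]
  if (length(ii$idx)) avail[ii$idx] <- avail[ii$idx] - ii$w
  fi <- cn$in_frac[[ti]]
  if (length(fi$idx)) {
    d <- (credit[fi$fid] + fi$num) %/% fi$den
    avail[fi$idx] <- avail[fi$idx] - d
  }
  avail
}

sample_step <- function(cn, marking, credit) {
  avail <- marking
  counts <- integer(cn$nT)
  used_cap <- logical(cn$nT)
  repeat {
    en <- which(enabled_mask(cn, avail, used_cap))
    if (!length(en)) break
    ti <- if (length(en) == 1L) en else en[sample.int(length(en), 1L)]
    counts[ti] <- counts[ti] + 1L
    if (cn$capped[ti]) used_cap[ti] <- TRUE
    avail <- reserve_one(cn, avail, credit, ti)
  }
  counts
}

# Advance marking and credit by one step given the sampled firing counts.
# Returns the boundary marking, updated credit, and per-fractional-arc token
# transfer amounts for this step.
apply_step <- function(cn, marking, credit, counts) {
  prod <- integer(cn$nP)
  transfers <- integer(length(credit))
  for (ti in which(counts > 0L)) {
    k <- counts[ti]
    ii <- cn$in_int[[ti]]
    if (length(ii$idx)) marking[ii$idx] <- marking[ii$idx] - k * ii$w
    oo <- cn$out_int[[ti]]
    if (length(oo$idx)) prod[oo$idx] <- prod[oo$idx] + k * oo$w
    fi <- cn$in_frac[[ti]]
    if (length(fi$idx)) {
      c2 <- credit[fi$fid] + fi$num
      d <- c2 %/% fi$den
      credit[fi$fid] <- c2 %% fi$den
      marking[fi$idx] <- marking[fi$idx] - d
      transfers[fi$fid] <- transfers[fi$fid] + d
    }
    fo <- cn$out_frac[[ti]]
    if (length(fo$idx)) {
      c2 <- credit[fo$fid] + fo$num
      d <- c2 %/% fo$den
      credit[fo$fid] <- c2 %% fo$den
      prod[fo$idx] <- prod[fo$idx] + d
      transfers[fo$fid] <- transfers[fo$fid] + d
    }
  }
  marking <- marking + prod
  if (any(marking < 0L)) {
    stop("internal consistency error: negative token count after step")
  }
  list(marking = marking, credit = credit, transfers = transfers)
}

#' Is a transition enabled?
#'
#' A transition is enabled when every input place holds at least
#' `ceiling(weight)` tokens beyond what is already reserved by firings drawn
#' earlier in the current step. A fractional input arc therefore requires one
#' waiting token even on steps where its credit will not yet transfer.
#'
#' @param net A valid [petri_net()].
#' @param marking Named integer vector of token counts (defaults to the net's
#'   initial marking).
#' @param transition Transition name.
#' @param reserved Optional named integer vector of tokens already committed
#'   earlier in the step.
#' @return `TRUE` or `FALSE`.
#' @examples
#' net <- build_wnt_net(wnt_scenario(wnt = 5))
#' transition_enabled(net, transition = "t1")
#' @export
transition_enabled <- function(net, marking = NULL, transition,
                               reserved = NULL) {
  stop_if_invalid(net)
  cn <- compile_net(net)
  ti <- match(transition, cn$transitions)
  if (is.na(ti)) stop("unknown transition '", transition, "'")
  m <- marking_vector(net, marking)
  if (!is.null(reserved)) {
    m[names(reserved)] <- m[names(reserved)] - as.integer(reserved)
  }
  all(m >= cn$req[ti, ])
}

marking_vector <- function(net, marking) {
  if (is.null(marking)) return(net$marking)
  normalise_marking(marking, net$places)[net$places]
}

#' Sample one maximal firing multiset
#'
#' Builds the firing multiset for a single step by iterated uniform-random
#' reservation (see [simulate_net()] for the semantics). Uses R's current RNG
#' stream; call `set.seed()` first for reproducibility.
#'
#' @inheritParams transition_enabled
#' @param credit Optional named integer vector of fractional-arc credit
#'   numerators (names are `"source -> target"` keys); defaults to zero.
#' @return Named integer vector of firing counts, one entry per transition.
#'   After it is applied, no transition is enabled against the residual
#'   unreserved marking (maximality).
#' @export
sample_step_firing <- function(net, marking = NULL, credit = NULL) {
  stop_if_invalid(net)
  cn <- compile_net(net)
  cr <- credit_vector(cn, credit)
  counts <- sample_step(cn, marking_vector(net, marking), cr)
  stats::setNames(counts, cn$transitions)
}

credit_vector <- function(cn, credit) {
  cr <- stats::setNames(integer(length(cn$frac_keys)), cn$frac_keys)
  if (!is.null(credit)) {
    known <- intersect(names(credit), cn$frac_keys)
    cr[known] <- as.integer(credit[known])
  }
  cr
}

#' Apply a sampled firing to a marking
#'
#' Consumes and produces tokens for the given firing counts. Integer-weight
#' arcs move `weight` tokens per firing; each fractional arc adds its weight
#' to an exact credit and moves `floor(credit)` whole tokens, keeping the
#' remainder. Productions land at the step boundary.
#'
#' @inheritParams sample_step_firing
#' @param firing Named integer vector of firing counts, as returned by
#'   [sample_step_firing()].
#' @return A list with elements `marking` (named integer vector), `credit`
#'   (named integer numerator vector, always in `[0, den)`), and `transfers`
#'   (tokens moved by each fractional arc this step).
#' @export
apply_firing <- function(net, marking = NULL, firing, credit = NULL) {
  stop_if_invalid(net)
  cn <- compile_net(net)
  counts <- integer(cn$nT)
  known <- intersect(names(firing), cn$transitions)
  counts[match(known, cn$transitions)] <- as.integer(firing[known])
  res <- apply_step(cn, marking_vector(net, marking),
                    credit_vector(cn, credit), counts)
  list(marking = stats::setNames(res$marking, cn$places),
       credit = stats::setNames(res$credit, cn$frac_keys),
       transfers = stats::setNames(res$transfers, cn$frac_keys))
}

#' Simulate a Petri net under maximally parallel semantics
#'
#' Runs the token game for `steps` discrete steps from the net's initial
#' marking with all fractional credits at zero. The result is a pure function
#' of `(net, steps, seed)`.
#'
#' @param net A valid [petri_net()].
#' @param steps Positive integer number of steps.
#' @param seed Integer seed for the uniform conflict draws.
#' @return A `petri_trace`: list with `markings` (a `(steps+1) x n_places`
#'   integer matrix, row 1 = initial marking), `firings` (`steps x
#'   n_transitions` counts), `transfers` (`steps x n_fractional_arcs` token
#'   transfers) and `seed`. Use [tidy()] for a long tibble.
#' @examples
#' net <- build_wnt_net(wnt_scenario(gsk3 = 0))
#' tr <- simulate_net(net, steps = 20, seed = 1)
#' utils::tail(tidy(tr), 3)
#' @export
simulate_net <- function(net, steps, seed) {
  if (!is.numeric(steps) || length(steps) != 1L || steps <= 0 ||
      steps != round(steps)) {
    stop("`steps` must be a positive integer")
  }
  stop_if_invalid(net)
  steps <- as.integer(steps)
  cn <- compile_net(net)
  set.seed(as.integer(seed))
  simulate_compiled(cn, net$marking[cn$places], steps, seed)
}

# Core loop shared by simulate_net() and run_ensemble(); assumes the RNG
# stream is already positioned.
simulate_compiled <- function(cn, marking, steps, seed) {
  markings <- matrix(0L, nrow = steps + 1L, ncol = cn$nP,
                     dimnames = list(NULL, cn$places))
  firings <- matrix(0L, nrow = steps, ncol = cn$nT,
                    dimnames = list(NULL, cn$transitions))
  transfers <- matrix(0L, nrow = steps, ncol = length(cn$frac_keys),
                      dimnames = list(NULL, cn$frac_keys))
  credit <- integer(length(cn$frac_keys))
  markings[1L, ] <- marking
  for (s in seq_len(steps)) {
    counts <- sample_step(cn, marking, credit)
    res <- apply_step(cn, marking, credit, counts)
    marking <- res$marking
    credit <- res$credit
    markings[s + 1L, ] <- marking
    firings[s, ] <- counts
    transfers[s, ] <- res$transfers
  }
  structure(
    list(markings = markings, firings = firings, transfers = transfers,
         steps = steps, seed = seed, places = cn$places,
         transitions = cn$transitions),
    class = "petri_trace"
  )
}

#' @export
print.petri_trace <- function(x, ...) {
  cat("<petri_trace> ", x$steps, " steps over ", length(x$places),
      " places (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Ensemble simulation with per-step summary statistics
#'
#' Repeats [simulate_net()] for `replicates` independent runs and summarises
#' a scalar observable of the marking at every step. Replicate `r` uses seed
#' `(seed + r) mod (2^31 - 1)`, a fixed, logged derivation, so the ensemble
#' is a pure function of `(net, steps, replicates, seed)`.
#'
#' @inheritParams simulate_net
#' @param replicates Positive integer number of independent runs.
#' @param observable Function mapping a named marking vector to one number;
#'   defaults to the total token count.
#' @return An `ensemble_summary` tibble with columns `step` (0..steps),
#'   `mean` and `sd` (sample standard deviation, n-1 denominator; reported as
#'   0 with a warning when `replicates == 1`). The per-replicate observable
#'   matrix is attached as attribute `"values"`.
#' @examples
#' net <- build_wnt_net(wnt_scenario(gsk3 = 0))
#' run_ensemble(net, steps = 10, replicates = 5, seed = 1,
#'              observable = total_beta_catenin)
#' @export
run_ensemble <- function(net, steps, replicates, seed,
                         observable = function(m) sum(m)) {
  if (!is.numeric(replicates) || length(replicates) != 1L ||
      replicates <= 0 || replicates != round(replicates)) {
    stop("`replicates` must be a positive integer")
  }
  stop_if_invalid(net)
  steps <- as.integer(steps)
  replicates <- as.integer(replicates)
  cn <- compile_net(net)
  m0 <- net$marking[cn$places]
  values <- matrix(NA_real_, nrow = steps + 1L, ncol = replicates)
  for (r in seq_len(replicates)) {
    rseed <- (as.integer(seed) + r) %% 2147483647L
    set.seed(rseed)
    tr <- simulate_compiled(cn, m0, steps, rseed)
    values[, r] <- apply(tr$markings, 1L, observable)
  }
  if (replicates == 1L) {
    warning("single replicate: standard deviation reported as 0")
    sds <- rep(0, steps + 1L)
  } else {
    sds <- apply(values, 1L, stats::sd)
  }
  out <- tibble::tibble(
    step = 0:steps,
    mean = rowMeans(values),
    sd = sds
  )
  attr(out, "values") <- values
  attr(out, "replicates") <- replicates
  attr(out, "base_seed") <- as.integer(seed)
  class(out) <- c("ensemble_summary", class(out))
  out
}
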