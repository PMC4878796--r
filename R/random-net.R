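# Random net fixture generator for engine property tests.

#' Generate a random small Petri net
#'
#' Builds a connected bipartite net with integer arc weights (at most 3) and
#' a random initial marking, always passing [validate_net()]. Every
#' transition gets at least one input and one output place. With
#' `conservative = TRUE` each transition's total output weight equals its
#' total input weight, so the total token count is invariant under
#' simulation — the standard fixture for conservation property tests.
#'
#' @param n_places,n_transitions Node counts (>= 1).
#' @param max_tokens Maximum initial tokens per place.
#' @param seed Integer seed.
#' @param conservative Force equal input/output weight sums per transition.
#' @return A valid [petri_net()].
#' @examples
#' net <- random_net(4, 3, max_tokens = 5, seed = 42)
#' nrow(validate_net(net))  # 0
#' @export
random_net <- function(n_places, n_transitions, max_tokens = 6, seed = 1,
                       conservative = FALSE) {
  stopifnot(n_places >= 1, n_transitions >= 1, max_tokens >= 0)
  set.seed(as.integer(seed))
  places <- paste0("P", seq_len(n_places))
  transitions <- paste0("T", seq_len(n_transitions))
  pick <- function(n) sample(places, min(n, n_places))
  rows <- vector("list", n_transitions)
  for (i in seq_len(n_transitions)) {
    t <- transitions[i]
    ins <- pick(sample.int(2L, 1L))
    in_w <- sample.int(3L, length(ins), replace = TRUE)
    if (conservative) {
      total <- sum(in_w)
      outs <- pick(sample.int(min(2L, total), 1L))
      # random composition of `total` over the chosen output places
      out_w <- as.integer(tabulate(sample.int(length(outs), total,
                                              replace = TRUE),
                                   nbins = length(outs)))
      keep <- out_w > 0L
      outs <- outs[keep]
      out_w <- out_w[keep]
    } else {
      outs <- pick(sample.int(2L, 1L))
      out_w <- sample.int(3L, length(outs), replace = TRUE)
    }
    rows[[i]] <- tibble::tibble(
      source = c(ins, rep(t, length(outs))),
      target = c(rep(t, length(ins)), outs),
      weight = c(in_w, out_w)
    )
  }
  arcs <- dplyr::bind_rows(rows)
  # connect any place untouched so far through an extra conservative loop
  # on the first transition
  loose <- setdiff(places, unique(c(arcs$source, arcs$target)))
  for (p in loose) {
    key_in <- arc_key(p, transitions[1])
    key_out <- arc_key(transitions[1], p)
    keys <- arc_key(arcs$source, arcs$target)
    if (!key_in %in% keys && !key_out %in% keys) {
      arcs <- dplyr::bind_rows(
        arcs,
        tibble::tibble(source = c(p, transitions[1]),
                       target = c(transitions[1], p), weight = c(1, 1))
      )
    }
  }
  marking <- stats::setNames(
    sample.int(max_tokens + 1L, n_places, replace = TRUE) - 1L, places
  )
  net <- petri_net(arcs, places = places, transitions = transitions,
                   marking = marking)
  stop_if_invalid(net)
  net
}
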