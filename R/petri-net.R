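#' Construct a place/transition Petri net
#'
#' A Petri net is a bipartite graph: places (entities such as genes, proteins
#' or complexes) hold non-negative integer token counts, transitions (events
#' such as complex formation or gene expression) consume tokens from their
#' input places and produce tokens in their output places, and weighted
#' directed arcs connect the two node classes. Integer arc weights are tokens
#' per firing; fractional weights in (0, 1) encode rate-limited transfer (see
#' [simulate_net()]).
#'
#' The constructor is deliberately permissive: it normalises its inputs and
#' attaches them, while every structural rule (bipartiteness, dangling
#' endpoints, duplicate arcs, weight signs, marking coverage) is checked by
#' [validate_net()], which reports rather than throws so that broken nets can
#' be inspected.
#'
#' @param arcs A data frame with columns `source`, `target` and `weight`
#'   (numeric, or character accepted by [parse_weight()]).
#' @param places Character vector of place names.
#' @param transitions Character vector of transition names.
#' @param marking Initial marking: a named integer vector or a data frame with
#'   columns `place` and `tokens`. Unlisted places default to 0 tokens.
#' @param zero_ok Character vector of arc keys (`"source -> target"`) for
#'   which a weight of exactly 0 is deliberate and legal.
#' @return An object of class `petri_net` with elements `places`,
#'   `transitions`, `arcs` (tibble with exact `num`/`den` columns) and
#'   `marking` (named integer vector).
#' @seealso [validate_net()], [simulate_net()], [build_wnt_net()]
#' @examples
#' arcs <- tibble::tibble(source = c("a", "t"), target = c("t", "b"),
#'                        weight = c(1, 1))
#' net <- petri_net(arcs, places = c("a", "b"), transitions = "t",
#'                  marking = c(a = 3))
#' validate_net(net)
#' @export
petri_net <- function(arcs, places, transitions, marking = NULL,
                      zero_ok = character()) {
  stopifnot(is.data.frame(arcs) || is.null(arcs))
  if (is.null(arcs)) {
    arcs <- tibble::tibble(source = character(), target = character(),
                           weight = numeric())
  }
  req <- c("source", "target", "weight")
  if (!all(req %in% names(arcs))) {
    stop("`arcs` needs columns source, target, weight")
  }
  places <- as.character(places)
  transitions <- as.character(transitions)
  w <- parse_weight(arcs$weight)
  arcs <- tibble::tibble(
    source = as.character(arcs$source),
    target = as.character(arcs$target),
    weight = w$num / w$den,
    num = w$num,
    den = w$den
  )
  structure(
    list(
      places = places,
      transitions = transitions,
      arcs = arcs,
      marking = normalise_marking(marking, places),
      zero_ok = as.character(zero_ok)
    ),
    class = "petri_net"
  )
}

# Named integer vector covering `places`; extra names are kept so the
# validator can flag them.
normalise_marking <- function(marking, places) {
  m <- stats::setNames(rep(0L, length(places)), places)
  if (is.null(marking)) return(m)
  if (is.data.frame(marking)) {
    marking <- stats::setNames(marking$tokens, marking$place)
  }
  if (is.null(names(marking))) stop("`marking` must be named by place")
  extra <- setdiff(names(marking), places)
  m[names(marking)[names(marking) %in% places]] <-
    as.integer(marking[names(marking) %in% places])
  if (length(extra)) {
    m <- c(m, stats::setNames(as.integer(marking[extra]), extra))
  }
  m
}

arc_key <- function(source, target) paste(source, "->", target)

#' @export
print.petri_net <- function(x, ...) {
  cat("<petri_net> ", length(x$places), " places, ",
      length(x$transitions), " transitions, ", nrow(x$arcs), " arcs\n",
      sep = "")
  cat("tokens:", sum(x$marking), "in initial marking\n")
  invisible(x)
}

#' Check every structural invariant of a Petri net
#'
#' Runs all structural rules and returns one row per violation; an empty
#' report means the net is valid. Never throws on an invalid net, and is
#' idempotent and side-effect free.
#'
#' Rules: place/transition name spaces disjoint and non-empty; every arc
#' endpoint exists; every arc joins a place and a transition (bipartite); no
#' duplicate source -> target pair; weights non-negative, and zero only for
#' arcs the net declares in its `zero_ok` set; the marking covers exactly the
#' places with non-negative integer counts.
#'
#' @param net A [petri_net()].
#' @return A tibble with columns `rule`, `element`, `message`; zero rows iff
#'   valid.
#' @examples
#' bad <- petri_net(tibble::tibble(source = "a", target = "b", weight = 1),
#'                  places = c("a", "b"), transitions = "t")
#' validate_net(bad)  # flags the place -> place arc
#' @export
validate_net <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  rule <- character()
  element <- character()
  message <- character()
  flag <- function(r, e, m) {
    rule <<- c(rule, r)
    element <<- c(element, e)
    message <<- c(message, m)
  }

  if (any(!nzchar(net$places))) flag("empty-name", "", "empty place name")
  if (any(!nzchar(net$transitions))) flag("empty-name", "", "empty transition name")
  dupp <- unique(net$places[duplicated(net$places)])
  for (p in dupp) flag("duplicate-node", p, "place name repeated")
  dupt <- unique(net$transitions[duplicated(net$transitions)])
  for (t in dupt) flag("duplicate-node", t, "transition name repeated")
  both <- intersect(net$places, net$transitions)
  for (b in both) {
    flag("disjoint-names", b, "name used for both a place and a transition")
  }

  a <- net$arcs
  keys <- arc_key(a$source, a$target)
  for (k in unique(keys[duplicated(keys)])) {
    flag("duplicate-arc", k, "same source -> target pair appears twice")
  }
  for (i in seq_len(nrow(a))) {
    s_pl <- a$source[i] %in% net$places
    s_tr <- a$source[i] %in% net$transitions
    t_pl <- a$target[i] %in% net$places
    t_tr <- a$target[i] %in% net$transitions
    k <- keys[i]
    if (!s_pl && !s_tr) flag("dangling-endpoint", k, "unknown source node")
    if (!t_pl && !t_tr) flag("dangling-endpoint", k, "unknown target node")
    if ((s_pl || s_tr) && (t_pl || t_tr) && !xor(s_pl, t_pl)) {
      flag("bipartiteness", k,
           "arc must join one place and one transition")
    }
    if (a$num[i] < 0L) flag("negative-weight", k, "arc weight is negative")
    if (a$num[i] == 0L && !(k %in% net$zero_ok)) {
      flag("zero-weight", k, "arc weight is zero")
    }
  }

  m <- net$marking
  for (p in setdiff(net$places, names(m))) {
    flag("marking-missing", p, "no token count for place")
  }
  for (p in setdiff(names(m), net$places)) {
    flag("marking-unknown", p, "marking entry for unknown place")
  }
  bad <- names(m)[is.na(m) | m < 0L]
  for (p in bad) flag("marking-negative", p, "token count must be >= 0")

  tibble::tibble(rule = rule, element = element, message = message)
}

stop_if_invalid <- function(net) {
  rep <- validate_net(net)
  if (nrow(rep)) {
    stop("invalid Petri net: ",
         paste(sprintf("[%s] %s (%s)", rep$rule, rep$element, rep$message),
               collapse = "; "))
  }
  invisible(net)
}

incident_arcs <- function(net, t, direction) {
  stopifnot(inherits(net, "petri_net"))
  if (!t %in% net$transitions) {
    stop("unknown transition '", t, "'")
  }
  a <- net$arcs
  sel <- if (direction == "in") a$target == t else a$source == t
  a <- a[sel, , drop = FALSE]
  tibble::tibble(
    place = if (direction == "in") a$source else a$target,
    weight = a$weight, num = a$num, den = a$den
  )
}

#' Input and output places of a transition
#'
#' Partitions the arcs incident to a transition by direction. Weights are the
#' exact stored rationals (`num`/`den` columns), not rounded.
#'
#' @param net A [petri_net()].
#' @param transition Transition name.
#' @return A tibble with columns `place`, `weight`, `num`, `den`.
#' @examples
#' net <- build_wnt_net()
#' inputs_of(net, "t9")   # the beta-catenin gene place, weight 1
#' outputs_of(net, "t9")  # gene place (read-arc return) and protein place
#' @export
inputs_of <- function(net, transition) incident_arcs(net, transition, "in")

#' @rdname inputs_of
#' @export
outputs_of <- function(net, transition) incident_arcs(net, transition, "out")

#' Initial marking as a tidy tibble
#'
#' @param net A [petri_net()].
#' @return A tibble with columns `place`, `tokens`.
#' @export
initial_marking <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  tibble::tibble(place = names(net$marking),
                 tokens = as.integer(net$marking))
}
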