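# The curated Wnt/beta-catenin network.
#
# 18 places, 11 transitions, 41 arcs. Receptor module: WNT binds FZD and LRP
# (t1), DVL joins (t2), AXIN is sequestered into the signalosome (t3), which
# dissociates slowly (t4, all arcs weight 0.1 = once per ten steps).
# Destruction module: AXIN/APC/CK1/GSK3 assemble the destruction complex
# (t5), which binds beta-catenin (t6) and degrades it, being either reused
# (t7) or dissociated back into components (t8). Expression module:
# beta-catenin is produced every step by its gene (t9, read-arc pattern),
# accumulates, translocates and binds TCF/LEF (t10, needs 3 tokens, consumes
# 1), and the complex drives AXIN2 transcription (t11), whose product
# replenishes the AXIN pool at the feedback weight.

WNT_PLACES <- c(
  "WNT", "FZD", "LRP", "WNT/FZD/LRP", "DVL", "WNT/FZD/LRP/DVL",
  "AXIN", "signalosome", "APC", "CK1", "GSK3", "DC", "DC-CTNNB1",
  "CTNNB1_gene", "CTNNB1_protein", "TCF/LEF", "TCF/LEF-CTNNB1", "AXIN2_gene"
)

WNT_TRANSITIONS <- paste0("t", 1:11)

BETA_CATENIN_PLACES <- c("CTNNB1_protein", "DC-CTNNB1", "TCF/LEF-CTNNB1")

#' Define a Wnt/beta-catenin simulation scenario
#'
#' A scenario bundles the tunable knobs of the network: the initial WNT and
#' GSK3 token levels (0--5; wildtype is WNT 0, GSK3 5), the AXIN2 negative
#' feedback strength (the weight of the t11 -> AXIN arc, 0 = no feedback,
#' 0.15 = maximal feedback, i.e. three AXIN tokens per 20 transcription
#' steps), and the destruction-complex production weight on t5 (1 = wildtype;
#' 0.2, 0.1, 0.05 model APC inactivating mutations producing one complex per
#' 5, 10 or 20 steps; 0 is a complete null mutation).
#'
#' @param wnt,gsk3 Initial token levels, integers in 0--5.
#' @param axin2_feedback Rational weight in `[0, 0.15]` of the t11 -> AXIN
#'   arc.
#' @param apc_weight Destruction-complex production weight, one of
#'   1, 0.2, 0.1, 0.05, 0.
#' @param steps,replicates Simulation length and ensemble size (defaults 100
#'   and 100).
#' @param seed Integer base seed.
#' @return A `wnt_scenario` list.
#' @examples
#' wnt_scenario()              # wildtype
#' wnt_scenario(wnt = 5)       # maximal WNT stimulation
#' wnt_scenario(gsk3 = 0)      # complete GSK3 inhibition
#' @export
wnt_scenario <- function(wnt = 0, gsk3 = 5, axin2_feedback = 0,
                         apc_weight = 1, steps = 100, replicates = 100,
                         seed = 1) {
  if (!wnt %in% 0:5) stop("`wnt` must be an integer between 0 and 5")
  if (!gsk3 %in% 0:5) stop("`gsk3` must be an integer between 0 and 5")
  fb <- parse_weight(axin2_feedback)
  if (fb$num < 0L || fb$num / fb$den > 0.15) {
    stop("`axin2_feedback` must lie in [0, 0.15]")
  }
  if (!apc_weight %in% c(1, 0.2, 0.1, 0.05, 0)) {
    stop("`apc_weight` must be one of 1, 0.2, 0.1, 0.05, 0")
  }
  if (steps < 1 || replicates < 1) {
    stop("`steps` and `replicates` must be positive")
  }
  structure(
    list(wnt = as.integer(wnt), gsk3 = as.integer(gsk3),
         axin2_feedback = axin2_feedback, apc_weight = apc_weight,
         steps = as.integer(steps), replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "wnt_scenario"
  )
}

#' @export
print.wnt_scenario <- function(x, ...) {
  cat("<wnt_scenario> WNT =", x$wnt, "| GSK3 =", x$gsk3,
      "| AXIN2 feedback =", x$axin2_feedback,
      "| DC production weight =", x$apc_weight, "\n")
  cat(" ", x$steps, "steps x", x$replicates, "replicates, seed", x$seed, "\n")
  invisible(x)
}

#' Build the Wnt/beta-catenin Petri net
#'
#' Constructs the 18-place, 11-transition, 41-arc network for a given
#' scenario. The t11 -> AXIN feedback arc always exists (weight 0 makes it
#' inert, it transfers nothing and never blocks enabling). When `apc_weight
#' < 1` (APC mutant mode) t5 gains four return arcs of weight `1 -
#' apc_weight` back to AXIN, APC, CK1 and GSK3, so that per `1/apc_weight`
#' firings exactly one destruction complex forms while the components are
#' otherwise returned.
#'
#' Initial marking: FZD, LRP, DVL, AXIN, APC, CK1 = 5; WNT and GSK3 from the
#' scenario; TCF/LEF and both gene places = 1; every complex and the
#' beta-catenin protein pool = 0.
#'
#' @param scenario A [wnt_scenario()]; defaults to wildtype.
#' @return A valid [petri_net()].
#' @examples
#' net <- build_wnt_net()
#' length(net$places)      # 18
#' nrow(net$arcs)          # 41
#' @export
build_wnt_net <- function(scenario = wnt_scenario()) {
  stopifnot(inherits(scenario, "wnt_scenario"))
  w_apc <- scenario$apc_weight
  w_fb <- scenario$axin2_feedback
  arc <- function(source, target, weight = 1) {
    tibble::tibble(source = source, target = target, weight = weight)
  }
  arcs <- dplyr::bind_rows(
    # t1: WNT + FZD + LRP -> WNT/FZD/LRP
    arc(c("WNT", "FZD", "LRP"), "t1"), arc("t1", "WNT/FZD/LRP"),
    # t2: + DVL
    arc(c("WNT/FZD/LRP", "DVL"), "t2"), arc("t2", "WNT/FZD/LRP/DVL"),
    # t3: + AXIN -> signalosome
    arc(c("WNT/FZD/LRP/DVL", "AXIN"), "t3"), arc("t3", "signalosome"),
    # t4: slow signalosome dissociation, once per ten steps
    arc("signalosome", "t4", 0.1),
    arc("t4", c("WNT/FZD/LRP/DVL", "AXIN"), 0.1),
    # t5: destruction complex formation
    arc(c("AXIN", "APC", "CK1", "GSK3"), "t5"),
    arc("t5", "DC", w_apc),
    # t6: DC binds beta-catenin
    arc(c("DC", "CTNNB1_protein"), "t6"), arc("t6", "DC-CTNNB1"),
    # t7: degradation with DC reuse
    arc("DC-CTNNB1", "t7"), arc("t7", "DC"),
    # t8: degradation with DC dissociation
    arc("DC-CTNNB1", "t8"), arc("t8", c("AXIN", "APC", "CK1", "GSK3")),
    # t9: constitutive beta-catenin expression (read-arc gene pattern)
    arc("CTNNB1_gene", "t9"), arc("t9", c("CTNNB1_gene", "CTNNB1_protein")),
    # t10: nuclear translocation and TCF/LEF binding (needs 3, consumes 1)
    arc("CTNNB1_protein", "t10", 3), arc("TCF/LEF", "t10"),
    arc("t10", "CTNNB1_protein", 2), arc("t10", "TCF/LEF"),
    arc("t10", "TCF/LEF-CTNNB1"),
    # t11: AXIN2 transcription (read arcs on activator complex and gene)
    arc(c("TCF/LEF-CTNNB1", "AXIN2_gene"), "t11"),
    arc("t11", c("TCF/LEF-CTNNB1", "AXIN2_gene")),
    arc("t11", "AXIN", w_fb)
  )
  zero_ok <- character()
  if (parse_weight(w_fb)$num == 0L) {
    zero_ok <- c(zero_ok, arc_key("t11", "AXIN"))
  }
  if (w_apc < 1) {
    arcs <- dplyr::bind_rows(
      arcs,
      arc("t5", c("AXIN", "APC", "CK1", "GSK3"), 1 - w_apc)
    )
    if (w_apc == 0) zero_ok <- c(zero_ok, arc_key("t5", "DC"))
  }
  marking <- c(
    WNT = scenario$wnt, FZD = 5L, LRP = 5L, DVL = 5L,
    AXIN = 5L, APC = 5L, CK1 = 5L, GSK3 = scenario$gsk3,
    "CTNNB1_gene" = 1L, "TCF/LEF" = 1L, "AXIN2_gene" = 1L
  )
  net <- petri_net(arcs, places = WNT_PLACES, transitions = WNT_TRANSITIONS,
                   marking = marking, zero_ok = zero_ok)
  stop_if_invalid(net)
  net
}

#' Total beta-catenin observable
#'
#' Sum of the free beta-catenin pool, beta-catenin bound to the destruction
#' complex, and beta-catenin bound to TCF/LEF. This is the quantity
#' summarised in every campaign.
#'
#' @param marking A named token-count vector (as stored in a `petri_trace`)
#'   or a tibble with columns `place` and `tokens`.
#' @return Non-negative integer.
#' @examples
#' total_beta_catenin(c("CTNNB1_protein" = 2, "DC-CTNNB1" = 1,
#'                      "TCF/LEF-CTNNB1" = 1))  # 4
#' @export
total_beta_catenin <- function(marking) {
  if (is.data.frame(marking)) {
    marking <- stats::setNames(marking$tokens, marking$place)
  }
  missing <- setdiff(BETA_CATENIN_PLACES, names(marking))
  if (length(missing)) {
    stop("marking lacks place(s): ", paste(missing, collapse = ", "))
  }
  sum(marking[BETA_CATENIN_PLACES])
}

#' Read a scenario from a YAML or JSON file
#'
#' The file holds any subset of the [wnt_scenario()] fields (`wnt`, `gsk3`,
#' `axin2_feedback`, `apc_weight`, `steps`, `replicates`, `seed`); omitted
#' fields take their wildtype defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `wnt_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("wnt", "gsk3", "axin2_feedback", "apc_weight", "steps",
             "replicates", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(wnt_scenario, cfg)
}
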