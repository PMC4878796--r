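# Exact rational arithmetic for arc weights.
#
# Fractional weights encode firing rates (0.1 = one token transfer per ten
# firings of the transition), so the credit bookkeeping in the engine must be
# exact over arbitrarily long runs: a credit is an integer numerator over the
# arc's own denominator and 0.1 + 0.1 + ... never drifts. Weights are parsed
# once into reduced num/den integer pairs and kept that way.

gcd_int <- function(a, b) {
  while (b != 0L) {
    tmp <- b
    b <- a %% b
    a <- tmp
  }
  a
}

#' Parse arc weights into exact rationals
#'
#' Accepts numerics (must be an exact multiple of 1/10000, which covers every
#' weight used in the Wnt model and any PNML decimal up to 4 places), decimal
#' strings of up to 6 decimal places, or `"p/q"` fraction strings. Returns
#' reduced numerator/denominator integer vectors.
#'
#' @param x numeric or character vector of weights.
#' @return A list with integer components `num` and `den` (den >= 1).
#' @examples
#' parse_weight(0.15)   # 3/20
#' parse_weight("0.1")  # 1/10
#' @export
parse_weight <- function(x) {
  n <- length(x)
  num <- integer(n)
  den <- integer(n)
  for (i in seq_len(n)) {
    xi <- x[[i]]
    if (is.character(xi)) {
      xi <- trimws(xi)
      if (grepl("^-?[0-9]+$", xi)) {
        num[i] <- as.integer(xi)
        den[i] <- 1L
      } else if (grepl("^-?[0-9]*\\.[0-9]{1,6}$", xi)) {
        neg <- startsWith(xi, "-")
        if (neg) xi <- substring(xi, 2L)
        parts <- strsplit(xi, ".", fixed = TRUE)[[1]]
        ip <- if (nzchar(parts[1])) as.integer(parts[1]) else 0L
        fp <- parts[2]
        k <- nchar(fp)
        d <- as.integer(10^k)
        v <- ip * d + as.integer(fp)
        num[i] <- if (neg) -v else v
        den[i] <- d
      } else if (grepl("^-?[0-9]+/[0-9]+$", xi)) {
        parts <- strsplit(xi, "/", fixed = TRUE)[[1]]
        num[i] <- as.integer(parts[1])
        den[i] <- as.integer(parts[2])
        if (den[i] == 0L) stop("zero denominator in weight '", x[[i]], "'")
      } else {
        stop("cannot parse weight '", xi, "' as a rational number")
      }
    } else {
      v <- round(xi * 10000)
      if (!is.finite(xi) || abs(v / 10000 - xi) > 1e-9) {
        stop("weight ", xi, " is not an exact multiple of 1/10000; ",
             "pass it as a string such as \"1/3\"")
      }
      num[i] <- as.integer(v)
      den[i] <- 10000L
    }
    if (num[i] != 0L) {
      g <- gcd_int(abs(num[i]), den[i])
      num[i] <- num[i] %/% g
      den[i] <- den[i] %/% g
    } else {
      den[i] <- 1L
    }
  }
  list(num = num, den = den)
}

# Render a reduced rational as the shortest exact decimal string (used for
# PNML inscriptions); falls back to "p/q" for non-decimal denominators.
weight_label <- function(num, den) {
  mapply(function(p, q) {
    if (q == 1L) return(as.character(p))
    for (k in 1:6) {
      scale <- as.integer(10^k)
      if ((p * scale) %% q == 0L) {
        v <- (p * scale) %/% q
        return(sprintf("%d.%0*d", v %/% scale, k, abs(v %% scale)))
      }
    }
    paste0(p, "/", q)
  }, num, den, USE.NAMES = FALSE)
}
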