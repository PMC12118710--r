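#' Parse a shorthand lipid species name
#'
#' Parses the compact lipidomics notation `CLASS C:D` with optional ether
#' prefix (`O-`, `P-`), optional per-chain lists separated by `_` (chain
#' positions undefined) or `/` (positions defined), and optional `;`
#' modifiers such as `2O`, `O` or `S` attached to a chain or to the sum
#' composition. Examples: `"TG 58:9"`, `"PC 18:1_20:3"`,
#' `"Cer 18:1;2O/23:0"`, `"ST 28:1;O;S"`.
#'
#' Modifiers are kept as opaque ordered tokens; no chemistry is inferred
#' from them. When individual chains are given, the sum composition is the
#' element-wise sum over chains.
#'
#' @param name a single lipid species name.
#' @return an object of class `lipid_name` with fields `lipid_class`,
#'   `ether_prefix` (`NA`, `"O-"` or `"P-"`), `chains` (data.frame with
#'   columns `carbons`, `double_bonds`, `modifiers`), `separator`
#'   (`"sum"`, `"_"` or `"/"`), `total_carbons`, `total_double_bonds`.
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("lipid name must be a single non-empty string", call. = FALSE)
  s <- trimws(name)
  m <- regexec("^([A-Za-z][A-Za-z0-9]*) +(O-|P-)?(.+)$", s)[[1]]
  if (m[1] == -1)
    stop(sprintf("cannot parse lipid name: '%s'", s), call. = FALSE)
  grab <- function(i) {
    if (m[i + 1] == -1 || attr(m, "match.length")[i + 1] == 0) return(NA_character_)
    substr(s, m[i + 1], m[i + 1] + attr(m, "match.length")[i + 1] - 1)
  }
  cls <- grab(1); prefix <- grab(2); comp <- grab(3)

  has_slash <- grepl("/", comp, fixed = TRUE)
  has_us <- grepl("_", comp, fixed = TRUE)
  if (has_slash && has_us)
    stop(sprintf("mixed chain separators in '%s'", s), call. = FALSE)
  sep <- if (has_slash) "/" else if (has_us) "_" else "sum"
  chunks <- if (sep == "sum") comp else strsplit(comp, sep, fixed = TRUE)[[1]]

  parse_chain <- function(ch) {
    cm <- regexec("^([0-9]+):([0-9]+)((?:;[A-Za-z0-9]+)*)$", ch)[[1]]
    if (cm[1] == -1)
      stop(sprintf("cannot parse chain token '%s' in '%s'", ch, s), call. = FALSE)
    pick <- function(i) substr(ch, cm[i + 1], cm[i + 1] + attr(cm, "match.length")[i + 1] - 1)
    mods <- pick(3)
    mods <- if (nzchar(mods)) sub("^;", "", mods) else ""
    list(carbons = as.integer(pick(1)), double_bonds = as.integer(pick(2)),
         modifiers = mods)
  }
  parsed <- lapply(chunks, parse_chain)
  chains <- data.frame(
    carbons = vapply(parsed, `[[`, integer(1), "carbons"),
    double_bonds = vapply(parsed, `[[`, integer(1), "double_bonds"),
    modifiers = vapply(parsed, `[[`, character(1), "modifiers"),
    stringsAsFactors = FALSE)

  structure(list(
    lipid_class = cls,
    ether_prefix = prefix,
    chains = chains,
    separator = sep,
    total_carbons = sum(chains$carbons),
    total_double_bonds = sum(chains$double_bonds)
  ), class = "lipid_name")
}

#' Canonical shorthand string for a parsed lipid name
#'
#' `parse_lipid_name(format_lipid_name(x))` reproduces `x`.
#'
#' @param x a `lipid_name`.
#' @return character scalar.
#' @export
format_lipid_name <- function(x) {
  stopifnot(inherits(x, "lipid_name"))
  chunk <- function(i) {
    base <- sprintf("%d:%d", x$chains$carbons[i], x$chains$double_bonds[i])
    mods <- x$chains$modifiers[i]
    if (nzchar(mods)) paste0(base, ";", gsub(";", ";", mods)) else base
  }
  body <- paste(vapply(seq_len(nrow(x$chains)), chunk, character(1)),
                collapse = if (x$separator == "sum") "" else x$separator)
  prefix <- if (is.na(x$ether_prefix)) "" else x$ether_prefix
  paste0(x$lipid_class, " ", prefix, body)
}

#' @export
print.lipid_name <- function(x, ...) {
  cat(format_lipid_name(x), "\n")
  cat(sprintf("  class %s, total %d:%d, chains %s\n", x$lipid_class,
              x$total_carbons, x$total_double_bonds,
              if (x$separator == "sum") "unresolved (sum composition)"
              else sprintf("%d (%s positions)", nrow(x$chains),
                           if (x$separator == "/") "defined" else "undefined")))
  invisible(x)
}

#' Lipid class table with rhythmic counts
#'
#' Parses every species name, tallies species per lipid class and, in
#' parallel, how many of them carry a TRUE rhythmicity flag.
#'
#' @param names character vector of shorthand lipid names.
#' @param rhythmic logical vector aligned to `names`.
#' @return data.frame with columns `lipid_class`, `n_total`, `n_rhythmic`,
#'   ordered by decreasing `n_total`.
#' @export
lipid_class_distribution <- function(names, rhythmic = logical(length(names))) {
  if (length(names) != length(rhythmic))
    stop("'names' and 'rhythmic' must be aligned", call. = FALSE)
  if (!length(names))
    return(data.frame(lipid_class = character(0), n_total = integer(0),
                      n_rhythmic = integer(0)))
  cls <- vapply(names, function(nm) parse_lipid_name(nm)$lipid_class, character(1))
  tot <- table(cls)
  rhy <- tapply(rhythmic, cls, sum)
  out <- data.frame(lipid_class = names(tot),
                    n_total = as.integer(tot),
                    n_rhythmic = as.integer(rhy[names(tot)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_total, out$lipid_class), , drop = FALSE]
}

# Random valid shorthand name under the grammar; used by the lipidome
# generator and by the parser round-trip property test.
random_lipid_name <- function(class_palette, max_chains = 3) {
  cls <- sample(class_palette, 1)
  n_chain_pool <- c(TG = 3, DG = 2, PC = 2, PE = 2, PG = 2, PI = 2, PS = 2,
                    Cer = 2, SM = 2, CE = 1, ST = 1, FFA = 1, LPC = 1, LPE = 1)
  k_max <- min(max_chains, n_chain_pool[cls] %||% 2)
  if (is.na(k_max)) k_max <- 2
  sum_only <- runif(1) < 0.5 || k_max == 1
  prefix <- if (cls %in% c("PC", "PE") && runif(1) < 0.15)
    sample(c("O-", "P-"), 1) else NA_character_
  mk_chain <- function() {
    c_n <- sample(12:24, 1)
    d_n <- sample(0:6, 1)
    mods <- if (cls %in% c("Cer", "SM", "ST") && runif(1) < 0.5) {
      paste(sample(c("2O", "O", "S"), sample(1:2, 1)), collapse = ";")
    } else ""
    list(carbons = c_n, double_bonds = d_n, modifiers = mods)
  }
  if (sum_only) {
    k <- max(1, k_max)
    ch <- mk_chain()
    ch$carbons <- ch$carbons * k            # plausible total for the class
    chains <- data.frame(carbons = ch$carbons, double_bonds = ch$double_bonds,
                         modifiers = ch$modifiers, stringsAsFactors = FALSE)
    sep <- "sum"
  } else {
    k <- k_max
    lst <- replicate(k, mk_chain(), simplify = FALSE)
    chains <- data.frame(
      carbons = vapply(lst, `[[`, numeric(1), "carbons"),
      double_bonds = vapply(lst, `[[`, numeric(1), "double_bonds"),
      modifiers = vapply(lst, `[[`, character(1), "modifiers"),
      stringsAsFactors = FALSE)
    sep <- sample(c("_", "/"), 1)
  }
  x <- structure(list(lipid_class = cls, ether_prefix = prefix,
                      chains = chains, separator = sep,
                      total_carbons = sum(chains$carbons),
                      total_double_bonds = sum(chains$double_bonds)),
                 class = "lipid_name")
  format_lipid_name(x)
}
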