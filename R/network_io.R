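# Plain-text network format
#
#   # comment
#   [SPECIES]
#   id <tab-or-pipe> compartment <tab-or-pipe> initial_value <tab-or-pipe> synthesized
#   [REACTIONS]
#   id | reactants -> products | rate_constant
#   id | reactants <-> products | k_forward, k_reverse
#
# Reactant/product sides are "+"-separated terms with optional integer
# coefficients written as "2*A"; an empty side is written "0" (zero-order
# production or pure degradation). Reversible arrows are syntactic sugar:
# the loader always expands them into two irreversible reactions, so
# parameter vectors index irreversible reactions only.

split_fields <- function(line) {
  fields <- if (grepl("|", line, fixed = TRUE)) {
    strsplit(line, "|", fixed = TRUE)[[1]]
  } else {
    strsplit(line, "\t", fixed = TRUE)[[1]]
  }
  fields <- trimws(fields)
  fields[nzchar(fields)]
}

parse_side <- function(txt, path, lineno) {
  txt <- trimws(txt)
  if (txt %in% c("", "0", "-")) {
    return(tibble::tibble(id = character(), coef = integer()))
  }
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  coef <- rep(1L, length(terms))
  id <- terms
  hit <- grepl("*", terms, fixed = TRUE)
  if (any(hit)) {
    parts <- strsplit(terms[hit], "*", fixed = TRUE)
    coef[hit] <- vapply(parts, function(p) {
      v <- suppressWarnings(as.integer(trimws(p[1])))
      if (is.na(v) || v < 1L) {
        abort(paste0(path, ":", lineno, ": bad stoichiometric coefficient in '", txt, "'"))
      }
      v
    }, integer(1))
    id[hit] <- vapply(parts, function(p) trimws(p[2]), character(1))
  }
  # repeated species on one side accumulate (e.g. "Ra + Ra")
  agg <- tapply(coef, factor(id, levels = unique(id)), sum)
  tibble::tibble(id = names(agg), coef = as.integer(agg))
}

classify_reaction <- function(reactants, products) {
  if (nrow(reactants) == 0L) return("zero-order")
  if (length(intersect(reactants$id, products$id))) return("catalytic")
  if (sum(reactants$coef) >= 2L) return("association")
  "dissociation"
}

#' Read a reaction network from the flat text format
#'
#' Parses the `[SPECIES]` / `[REACTIONS]` sections (tab- or pipe-delimited,
#' `#` comments), expands every reversible `<->` reaction into a forward and
#' a reverse irreversible step, and validates the result. Species and
#' reaction order equal file order.
#'
#' @param path path to a network file.
#' @return a [kin_network()].
#' @export
read_network <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  section <- NA_character_
  sp_rows <- list()
  rx_rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      section <- toupper(gsub("\\[|\\]", "", line))
      if (!section %in% c("SPECIES", "REACTIONS")) {
        abort(paste0(path, ":", ln, ": unknown section [", section, "]"))
      }
      next
    }
    if (is.na(section)) abort(paste0(path, ":", ln, ": content before any section header"))
    fields <- split_fields(line)
    if (section == "SPECIES") {
      if (length(fields) != 4L) {
        abort(paste0(path, ":", ln, ": species lines need 4 fields (id, compartment, initial_value, synthesized)"))
      }
      iv <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(iv) || iv < 0) abort(paste0(path, ":", ln, ": bad initial value '", fields[3], "'"))
      sp_rows[[length(sp_rows) + 1L]] <- tibble::tibble(
        id = fields[1], compartment = fields[2],
        initial_value = iv, synthesized = fields[4] %in% c("1", "TRUE", "true", "yes"))
    } else {
      if (length(fields) == 2L) fields <- c(paste0("r", length(rx_rows) + 1L), fields)
      if (length(fields) != 3L) {
        abort(paste0(path, ":", ln, ": reaction lines need 2 or 3 fields (id, equation, rate constants)"))
      }
      id <- fields[1]
      eq <- fields[2]
      kids <- trimws(strsplit(fields[3], ",", fixed = TRUE)[[1]])
      reversible <- grepl("<->", eq, fixed = TRUE)
      sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L) abort(paste0(path, ":", ln, ": cannot parse equation '", eq, "'"))
      lhs <- parse_side(sides[1], path, ln)
      rhs <- parse_side(sides[2], path, ln)
      if (reversible) {
        if (length(kids) != 2L) {
          abort(paste0(path, ":", ln, ": reversible reactions need 2 rate-constant ids"))
        }
        rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
          id = paste0(id, "_f"), rate_constant = kids[1],
          kind = classify_reaction(lhs, rhs),
          reactants = list(lhs), products = list(rhs), line = ln)
        rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
          id = paste0(id, "_r"), rate_constant = kids[2],
          kind = classify_reaction(rhs, lhs),
          reactants = list(rhs), products = list(lhs), line = ln)
      } else {
        if (length(kids) != 1L) {
          abort(paste0(path, ":", ln, ": irreversible reactions need exactly 1 rate-constant id"))
        }
        rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
          id = id, rate_constant = kids[1],
          kind = classify_reaction(lhs, rhs),
          reactants = list(lhs), products = list(rhs), line = ln)
      }
    }
  }
  if (!length(sp_rows)) abort(paste0(path, ": no [SPECIES] entries"))
  if (!length(rx_rows)) abort(paste0(path, ": no [REACTIONS] entries"))
  species <- dplyr::bind_rows(sp_rows)
  reactions <- dplyr::bind_rows(rx_rows)
  for (q in seq_len(nrow(reactions))) {
    unknown <- setdiff(c(reactions$reactants[[q]]$id, reactions$products[[q]]$id), species$id)
    if (length(unknown)) {
      abort(paste0(path, ":", reactions$line[q], ": undeclared species: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  reactions$line <- NULL
  kin_network(species, reactions)
}

format_side <- function(tbl) {
  if (nrow(tbl) == 0L) return("0")
  paste(ifelse(tbl$coef > 1L, paste0(tbl$coef, "*", tbl$id), tbl$id), collapse = " + ")
}

#' Write a network in the flat text format
#'
#' The expanded irreversible form is written; reading it back yields an
#' identical network.
#'
#' @param net a [kin_network()].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  sp <- net$species
  sp_lines <- sprintf("%s\t%s\t%.15g\t%d", sp$id, sp$compartment,
                      sp$initial_value, as.integer(sp$synthesized))
  rx <- net$reactions
  rx_lines <- vapply(seq_len(nrow(rx)), function(q) {
    paste(rx$id[q],
          paste(format_side(rx$reactants[[q]]), "->", format_side(rx$products[[q]])),
          rx$rate_constant[q], sep = " | ")
  }, character(1))
  writeLines(c("[SPECIES]", sp_lines, "[REACTIONS]", rx_lines), path)
  invisible(path)
}
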