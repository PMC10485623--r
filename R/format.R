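# Plain-text model format.
#
#   # comment
#   SPECIES <key> <kind>
#   RULE <target> <- ACT( term ; term ) INH( term ) [FROZEN: <expr>]
#   PRESPEC <term> -> <target> <+|->
#
# where <key> is `name` or `name@cell`, a term is `key` or `(key & key)`,
# and <expr> is TRUE or a disjunction of conjunctive clauses over literals
# (`!` for negation): `(!PTC | HH@1)`, `PTC & !HH@1 | ...`. Files written by
# write_boolean_model() round-trip bit-exactly through read_boolean_model().

fmt_term <- function(members) {
  if (length(members) == 1L) members
  else paste0("(", paste(members, collapse = " & "), ")")
}

fmt_terms <- function(terms) {
  ids <- vapply(terms, term_id, "")
  paste(vapply(terms[order(ids)], fmt_term, ""), collapse = " ; ")
}

fmt_frozen <- function(frozen) {
  if (isTRUE(frozen)) return("TRUE")
  cls <- vapply(frozen, function(cl) paste(sort(cl), collapse = " & "), "")
  paste(sort(cls), collapse = " | ")
}

#' Serialize a model to its text format
#'
#' @param model a [boolean_model()]
#' @param file optional output path; when `NULL` the lines are returned
#' @return character vector of lines, invisibly when writing to a file
#' @export
write_boolean_model <- function(model, file = NULL) {
  keys <- model_keys(model)
  lines <- c(sprintf("SPECIES %s %s", keys, model$species$kind))
  for (k in keys) {
    r <- model$rules[[k]]
    if (is.null(r)) next
    line <- sprintf("RULE %s <- ACT( %s ) INH( %s )", k,
                    fmt_terms(r$activators), fmt_terms(r$inhibitors))
    if (!is.null(r$frozen)) line <- paste0(line, " FROZEN: ", fmt_frozen(r$frozen))
    lines <- c(lines, gsub("\\(  \\)", "( )", line))
  }
  lines <- c(lines, sprintf("PRESPEC %s", sort(names(model$prespecified))))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

parse_term <- function(txt) {
  txt <- trimws(gsub("[()]", "", txt))
  trimws(strsplit(txt, "&", fixed = TRUE)[[1]])
}

parse_term_list <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(list())
  lapply(strsplit(txt, ";", fixed = TRUE)[[1]], parse_term)
}

parse_frozen <- function(txt) {
  txt <- trimws(txt)
  if (txt == "TRUE") return(TRUE)
  lapply(strsplit(txt, "|", fixed = TRUE)[[1]], function(cl)
    trimws(strsplit(gsub("[()]", "", cl), "&", fixed = TRUE)[[1]]))
}

#' Parse a model from its text format
#'
#' @param file path, or a character vector of lines via `text`
#' @param text optional character vector of lines (overrides `file`)
#' @return a [boolean_model()]
#' @export
read_boolean_model <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  src <- if (!is.null(file)) file else "<text>"
  lines_trim <- trimws(sub("#.*$", "", lines))
  sp <- list()
  rules <- list()
  pre <- character(0)
  for (i in seq_along(lines_trim)) {
    ln <- lines_trim[i]
    if (!nzchar(ln)) next
    fail <- function(msg) stop(sprintf("%s:%d: %s (\"%s\")", src, i, msg, lines[i]))
    if (startsWith(ln, "SPECIES ")) {
      f <- strsplit(trimws(sub("^SPECIES", "", ln)), "\\s+")[[1]]
      if (length(f) != 2L) fail("expected 'SPECIES <key> <kind>'")
      p <- parse_species_key(f[1])
      sp[[length(sp) + 1L]] <- data.frame(name = p$name, cell = p$cell,
                                          kind = f[2], stringsAsFactors = FALSE)
    } else if (startsWith(ln, "RULE ")) {
      mm <- regmatches(ln, regexec(
        "^RULE\\s+(\\S+)\\s*<-\\s*ACT\\((.*?)\\)\\s*INH\\((.*?)\\)\\s*(FROZEN:(.*))?$",
        ln))[[1]]
      if (length(mm) < 4L) fail("malformed RULE line")
      frozen <- if (nzchar(trimws(mm[6] %||% ""))) parse_frozen(mm[6]) else NULL
      rules[[mm[2]]] <- list(activators = parse_term_list(mm[3]),
                             inhibitors = parse_term_list(mm[4]),
                             frozen = frozen)
    } else if (startsWith(ln, "PRESPEC ")) {
      pre <- c(pre, trimws(sub("^PRESPEC", "", ln)))
    } else fail("unrecognized line")
  }
  if (!length(sp)) stop(src, ": no SPECIES lines found")
  species <- do.call(rbind, sp)
  boolean_model(species, rules = rules,
                prespecified = lapply(pre, parse_interaction_id))
}

# ---- BoolNet interoperability ---------------------------------------------

bn_name <- function(key) gsub("@", "_", key, fixed = TRUE)

bn_disjunct <- function(parts) {
  if (!length(parts)) return(NULL)
  paste(parts, collapse = " | ")
}

#' Export a model in BoolNet's `targets, factors` format
#'
#' Dominant-inhibition rules expand to `(a | b) & !(c | d)`; frozen clauses
#' are copied verbatim into the activator disjunction; external inputs map to
#' themselves. Cell suffixes `@c` become `_c` to satisfy BoolNet identifiers.
#'
#' @param model a [boolean_model()]
#' @param file output path
#' @export
write_boolnet <- function(model, file) {
  keys <- model_keys(model)
  lines <- "targets, factors"
  for (k in keys) {
    r <- model$rules[[k]]
    if (is.null(r)) {
      lines <- c(lines, paste0(bn_name(k), ", ", bn_name(k)))
      next
    }
    acts <- vapply(r$activators, function(t)
      if (length(t) > 1L) paste0("(", paste(bn_name(t), collapse = " & "), ")")
      else bn_name(t), "")
    if (isTRUE(r$frozen)) acts <- c(acts, "1")
    else if (!is.null(r$frozen))
      acts <- c(acts, vapply(r$frozen, function(cl) {
        lits <- ifelse(startsWith(cl, "!"),
                       paste0("!", bn_name(substring(cl, 2))), bn_name(cl))
        paste0("(", paste(lits, collapse = " & "), ")")
      }, ""))
    inhs <- vapply(r$inhibitors, function(t)
      if (length(t) > 1L) paste0("(", paste(bn_name(t), collapse = " & "), ")")
      else bn_name(t), "")
    expr <- if (!length(acts)) "0"
    else {
      a <- paste0("(", bn_disjunct(acts), ")")
      if (length(inhs)) paste0(a, " & !(", bn_disjunct(inhs), ")") else a
    }
    lines <- c(lines, paste0(bn_name(k), ", ", expr))
  }
  writeLines(lines, file)
  invisible(lines)
}
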