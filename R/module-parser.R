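## Recursive-descent parser for KEGG-style module DEFINITION expressions.
##
## Grammar (loosest to tightest binding):
##   steps   := alt (' ' alt)*          serial reaction steps -> AND
##   alt     := complex (',' complex)*  alternatives -> OR (any sufficient)
##   complex := ['-'] unit (('+'|'-') unit)*   enzyme complex -> AND;
##              a '-' marks the following unit OPTIONAL (non-essential)
##   unit    := KO | '--' | '(' steps ')'
## KO ids match K#####; '--' is an unspecified-component wildcard.

parseError <- function(message, offset) {
    stop(structure(class = c("magscore_parse_error", "error", "condition"),
                   list(message = sprintf("%s (at offset %d)",
                                          message, offset),
                        call = NULL, offset = offset)))
}

tokenizeDefinition <- function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    n <- length(chars)
    toks <- list()
    i <- 1L
    while (i <= n) {
        ch <- chars[i]
        if (grepl("^[[:space:]]$", ch)) {
            j <- i
            while (j <= n && grepl("^[[:space:]]$", chars[j])) j <- j + 1L
            toks[[length(toks) + 1L]] <- list(type = "SPACE", offset = i)
            i <- j
        } else if (ch %in% c("(", ")", ",", "+")) {
            type <- c("(" = "LPAREN", ")" = "RPAREN",
                      "," = "COMMA", "+" = "PLUS")[[ch]]
            toks[[length(toks) + 1L]] <- list(type = type, offset = i)
            i <- i + 1L
        } else if (ch == "-") {
            if (i < n && chars[i + 1L] == "-") {
                toks[[length(toks) + 1L]] <- list(type = "WILDCARD",
                                                  offset = i)
                i <- i + 2L
            } else {
                toks[[length(toks) + 1L]] <- list(type = "MINUS", offset = i)
                i <- i + 1L
            }
        } else if (grepl("^[[:alnum:]_]$", ch)) {
            j <- i
            while (j <= n && grepl("^[[:alnum:]_]$", chars[j])) j <- j + 1L
            word <- toupper(paste(chars[i:(j - 1L)], collapse = ""))
            if (!grepl(KO_PATTERN, word))
                parseError(sprintf("malformed KO token '%s'", word), i)
            toks[[length(toks) + 1L]] <- list(type = "KO", ko = word,
                                              offset = i)
            i <- j
        } else {
            parseError(sprintf("unexpected character '%s'", ch), i)
        }
    }
    toks
}

## token-stream state shared by the parse functions
newTokenStream <- function(tokens, textLen) {
    env <- new.env(parent = emptyenv())
    env$tokens <- tokens
    env$pos <- 1L
    env$textLen <- textLen
    env
}

tsPeek <- function(ts) {
    if (ts$pos > length(ts$tokens)) NULL else ts$tokens[[ts$pos]]
}

tsNext <- function(ts) {
    tok <- tsPeek(ts)
    ts$pos <- ts$pos + 1L
    tok
}

## style records surface syntax ("serial" for space-joined steps, "complex"
## for '+'-joined components) so serialization round-trips; scoring ignores it
mkAnd <- function(children, style = "serial") {
    if (length(children) == 1L) children[[1L]]
    else list(kind = "AND", style = style, children = children)
}

mkOr <- function(children) {
    if (length(children) == 1L) children[[1L]]
    else list(kind = "OR", children = children)
}

parseStepsFrom <- function(ts) {
    children <- list(parseAltFrom(ts))
    repeat {
        tok <- tsPeek(ts)
        if (is.null(tok) || tok$type != "SPACE") break
        tsNext(ts)
        nxt <- tsPeek(ts)
        if (is.null(nxt) || nxt$type == "RPAREN") break  # trailing blank
        children[[length(children) + 1L]] <- parseAltFrom(ts)
    }
    mkAnd(children)
}

parseAltFrom <- function(ts) {
    children <- list(parseComplexFrom(ts))
    repeat {
        tok <- tsPeek(ts)
        if (is.null(tok) || tok$type != "COMMA") break
        tsNext(ts)
        children[[length(children) + 1L]] <- parseComplexFrom(ts)
    }
    mkOr(children)
}

parseComplexFrom <- function(ts) {
    children <- list()
    optionalNext <- FALSE
    tok <- tsPeek(ts)
    if (!is.null(tok) && tok$type == "MINUS") {   # leading '-'
        tsNext(ts)
        optionalNext <- TRUE
    }
    repeat {
        unit <- parseUnitFrom(ts)
        if (optionalNext) unit <- list(kind = "OPTIONAL", child = unit)
        children[[length(children) + 1L]] <- unit
        optionalNext <- FALSE
        tok <- tsPeek(ts)
        if (is.null(tok) || !tok$type %in% c("PLUS", "MINUS")) break
        tsNext(ts)
        optionalNext <- tok$type == "MINUS"
    }
    mkAnd(children, style = "complex")
}

parseUnitFrom <- function(ts) {
    tok <- tsNext(ts)
    if (is.null(tok))
        parseError("unexpected end of definition", ts$textLen + 1L)
    switch(tok$type,
        KO = list(kind = "ATOM", ko = tok$ko),
        WILDCARD = list(kind = "WILDCARD"),
        LPAREN = {
            inner <- parseStepsFrom(ts)
            closing <- tsNext(ts)
            if (is.null(closing))
                parseError("unbalanced parenthesis: missing ')'",
                           ts$textLen + 1L)
            if (closing$type != "RPAREN")
                parseError("expected ')'", closing$offset)
            inner
        },
        parseError(sprintf("unexpected token '%s'", tok$type), tok$offset)
    )
}

#' Parse a metabolic module definition expression
#'
#' Parses a KEGG-style boolean DEFINITION string into a tree of reaction
#' steps. Spaces separate serial steps, commas separate alternatives of
#' which any one suffices, `+` joins the required components of an enzyme
#' complex, a `-` prefix marks a non-essential (optional) component, `--`
#' stands for an unspecified enzyme, and parentheses group. Operator
#' precedence from tightest to loosest: `+`/`-`, `,`, space.
#'
#' @param moduleId module accession, e.g. `"M00567"`.
#' @param definition the definition expression (non-empty).
#' @param name optional human-readable module name.
#' @return a [ModuleDefinition-class] object.
#' @examples
#' m <- parseModuleDefinition("M1", "K00399+K00401+K00402 (K00001,K00002)")
#' moduleSteps(m)
#' moduleCompletionScore(m, c("K00399", "K00401", "K00402", "K00002"))
#' @export
parseModuleDefinition <- function(moduleId, definition, name = "") {
    if (!is.character(definition) || length(definition) != 1L ||
        is.na(definition) || !nzchar(trimws(definition)))
        parseError("empty module definition", 1L)
    definition <- trimws(definition)
    toks <- tokenizeDefinition(definition)
    ts <- newTokenStream(toks, nchar(definition))
    root <- parseStepsFrom(ts)
    left <- tsPeek(ts)
    if (!is.null(left)) {
        if (left$type == "RPAREN")
            parseError("unbalanced parenthesis: unmatched ')'", left$offset)
        parseError("trailing input after definition", left$offset)
    }
    new("ModuleDefinition", moduleId = as.character(moduleId),
        name = as.character(name), root = root, sourceText = definition)
}

## ---- serialization (canonical form; '+'-complexes re-emitted as spaced
##      groups, which parse back to the identical AND tree) ----

serializeNode <- function(node) {
    wrapUnit <- function(child) {
        s <- serializeNode(child)
        if (child$kind %in% c("AND", "OR")) paste0("(", s, ")") else s
    }
    switch(node$kind,
        ATOM = node$ko,
        WILDCARD = "--",
        OPTIONAL = paste0("-", wrapUnit(node$child)),
        AND = if (identical(node$style, "complex")) {
            ## '+' before required components, '-' before optional ones
            parts <- vapply(seq_along(node$children), function(i) {
                child <- node$children[[i]]
                if (child$kind == "OPTIONAL")
                    paste0("-", wrapUnit(child$child))
                else paste0(if (i > 1L) "+", wrapUnit(child))
            }, character(1))
            paste(parts, collapse = "")
        } else {
            paste(vapply(node$children, wrapUnit, character(1)),
                  collapse = " ")
        },
        OR = paste(vapply(node$children, wrapUnit, character(1)),
                   collapse = ","),
        stop("unknown node kind: ", node$kind)
    )
}

#' Serialize a parsed module definition
#'
#' Emits a canonical definition string for a parsed module; re-parsing the
#' result yields a structurally identical expression tree (complexes written
#' with `+` in the source are re-emitted as parenthesized serial groups,
#' which denote the same all-required semantics).
#'
#' @param module a [ModuleDefinition-class].
#' @return a single definition string.
#' @export
serializeDefinition <- function(module) {
    stopifnot(is(module, "ModuleDefinition"))
    serializeNode(module@root)
}

#' Top-level reaction steps of a module
#'
#' @param module a [ModuleDefinition-class].
#' @return list of expression nodes, one per reaction step. Only these
#'   top-level units enter the module completion average; spaces nested
#'   inside parentheses contribute to their own group's mean instead.
#' @export
moduleSteps <- function(module) {
    stopifnot(is(module, "ModuleDefinition"))
    root <- module@root
    if (identical(root$kind, "AND") && !identical(root$style, "complex"))
        root$children else list(root)
}

collectKos <- function(node) {
    switch(node$kind,
        ATOM = node$ko,
        WILDCARD = character(0),
        OPTIONAL = collectKos(node$child),
        unique(unlist(lapply(node$children, collectKos)))
    )
}

#' All KO ids appearing in a module definition
#'
#' @param module a [ModuleDefinition-class].
#' @param includeOptional keep KOs that only occur inside optional
#'   components (default `TRUE`).
#' @return character vector of unique KO ids.
#' @export
moduleKos <- function(module, includeOptional = TRUE) {
    stopifnot(is(module, "ModuleDefinition"))
    if (includeOptional) return(unique(collectKos(module@root)))
    strip <- function(node) {
        switch(node$kind,
            ATOM = node$ko,
            WILDCARD = character(0),
            OPTIONAL = character(0),
            unique(unlist(lapply(node$children, strip))))
    }
    out <- strip(module@root)
    if (is.null(out)) character(0) else unique(out)
}

#' Does a module definition contain a wildcard component?
#' @param module a [ModuleDefinition-class].
#' @return `TRUE` if any `--` (unspecified enzyme) occurs in the definition.
#' @export
hasWildcard <- function(module) {
    stopifnot(is(module, "ModuleDefinition"))
    walk <- function(node) {
        switch(node$kind,
            WILDCARD = TRUE,
            ATOM = FALSE,
            OPTIONAL = walk(node$child),
            any(vapply(node$children, walk, logical(1))))
    }
    walk(module@root)
}
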