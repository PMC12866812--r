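#' @include AllClasses.R utils.R
NULL

## Shipped digit->unit bijections.
##
## The design-rule family deliberately *randomizes* the emitted sequence, so
## the default assignments must not preserve payload structure. For the
## power-of-two radices (B16, B4) base conversion is plain bit regrouping,
## and an order-preserving (lexicographic) assignment would leave constant
## bit regions as homopolymers; the shipped tables therefore use fixed
## scrambled bijections. The RInf-B4 table embeds the five published example
## assignments (after A: 3->C; after C: 1->G, 2->C; after G: 3->T;
## after T: 0->G) and fills the remaining cells so that constant-digit runs
## trace cycles over the bases (digit 0: A->G->C->A, digit 3: A->C->T->A,
## digit 1: the 4-cycle A->T->C->G) rather than homopolymers. The other
## tables were drawn once uniformly at random within their allowed-unit
## constraints (scratch generator seed 271828) and are frozen here.
.RULE_ROWS <- list(
    "RInf-B16" = list(
        A = c("CC","TG","GT","AT","CA","TA","TT","GA","TC","GG","AG","AA","AC","CG","GC","CT"),
        C = c("TG","CC","CA","TT","GG","AT","GC","GT","AG","AA","CG","GA","TA","AC","CT","TC"),
        G = c("TG","AA","CA","TA","AG","TT","CC","CG","GA","AC","AT","GC","TC","GG","GT","CT"),
        T = c("AT","GG","CG","GC","AC","CA","CT","TT","GA","AA","TA","GT","CC","AG","TG","TC")),
    "RInf-B4" = list(
        A = c("G","T","A","C"),
        C = c("A","G","C","T"),
        G = c("C","A","G","T"),
        T = c("G","C","T","A")),
    "R1-B12" = list(
        A = c("CG","TC","GC","AG","AT","CA","GA","TG","GT","CT","AC","TA"),
        C = c("CG","AG","TC","AC","CT","TG","CA","AT","TA","GA","GT","GC"),
        G = c("AT","CG","TA","CA","AC","TC","CT","GA","GC","TG","AG","GT"),
        T = c("GA","TC","TG","GC","CT","GT","AC","AG","TA","AT","CG","CA")),
    "R0-B9" = list(
        A = c("TA","TG","GA","GC","GT","CT","CG","TC","CA"),
        C = c("AT","GT","TG","AC","GC","TA","AG","TC","GA"),
        G = c("AG","CT","TG","TA","CA","AT","AC","CG","TC"),
        T = c("AT","CG","GT","CA","GA","GC","AC","AG","CT")),
    "R0-B3" = list(
        A = c("C","G","T"),
        C = c("G","T","A"),
        G = c("C","A","T"),
        T = c("A","G","C"))
)

.SCHEME_SPEC <- list(
    "simple"   = list(unitLen = 1L, radix = 4L,  maxRun = Inf, initiator = "",   guard = FALSE),
    "RInf-B16" = list(unitLen = 2L, radix = 16L, maxRun = Inf, initiator = "AT", guard = TRUE),
    "RInf-B4"  = list(unitLen = 1L, radix = 4L,  maxRun = Inf, initiator = "A",  guard = TRUE),
    "R1-B12"   = list(unitLen = 2L, radix = 12L, maxRun = 2,   initiator = "AT", guard = TRUE),
    "R0-B9"    = list(unitLen = 2L, radix = 9L,  maxRun = 1,   initiator = "AT", guard = TRUE),
    "R0-B3"    = list(unitLen = 1L, radix = 3L,  maxRun = 1,   initiator = "A",  guard = TRUE)
)

.SCHEME_ALIASES <- c(
    simple = "simple", R16 = "RInf-B16", R4 = "RInf-B4",
    R12 = "R1-B12", R9 = "R0-B9", R3 = "R0-B3",
    "RInf-B16" = "RInf-B16", "RInf-B4" = "RInf-B4",
    "R1-B12" = "R1-B12", "R0-B9" = "R0-B9", "R0-B3" = "R0-B3"
)

.resolveScheme <- function(scheme) {
    s <- as.character(scheme)[1L]
    s <- gsub("∞", "Inf", s)    # accept the infinity glyph
    if (!(s %in% names(.SCHEME_ALIASES)))
        stop("unknown scheme '", scheme, "'; known: ",
             paste(names(.SCHEME_SPEC), collapse = ", "))
    unname(.SCHEME_ALIASES[s])
}

#' Scheme identifiers of the shipped design rules
#'
#' @return character vector of the canonical scheme ids, the positional
#'   `simple` mapping first.
#' @examples dnastoreSchemes()
#' @export
dnastoreSchemes <- function() names(.SCHEME_SPEC)

#' Build a design-rule table
#'
#' Returns the shipped [RuleTable] for a scheme, optionally customised.
#' Allowed encoding units per context are: all 16 dimers (B16), the 12
#' heterodimers (B12), the 9 heterodimers whose first base differs from the
#' context base (B9), all 4 monomers (B4), and the 3 monomers differing from
#' the context base (B3). The shipped digit-to-unit bijections are fixed
#' scrambled assignments (see [RuleTable]); `rows` overrides allow loading
#' an external table (e.g. via [readRuleTableJSON()]) for bit-exact
#' agreement with a published table.
#'
#' @param scheme scheme id (`"simple"`, `"RInf-B16"`, `"RInf-B4"`,
#'   `"R1-B12"`, `"R0-B9"`, `"R0-B3"`; short aliases `R16`, `R4`, `R12`,
#'   `R9`, `R3` are accepted).
#' @param rows optional named list (contexts `A`,`C`,`G`,`T`) of ordered
#'   digit-to-unit assignments overriding the shipped bijections.
#' @param initiator optional initiator unit override.
#' @param guard optional guard-bit override.
#' @return a validated [RuleTable].
#' @examples
#' buildRuleTable("R0-B9")
#' @export
buildRuleTable <- function(scheme, rows = NULL, initiator = NULL, guard = NULL) {
    id <- .resolveScheme(scheme)
    spec <- .SCHEME_SPEC[[id]]
    tblRows <- if (id == "simple") {
        ## positional 2-bit map, one row repeated for interface uniformity
        rep(list(c("A", "C", "G", "T")), 4L) |> stats::setNames(.BASES)
    } else {
        .RULE_ROWS[[id]]
    }
    if (!is.null(rows)) {
        if (!is.list(rows) || is.null(names(rows)))
            stop("invalid table: 'rows' must be a named list of contexts")
        for (ctx in names(rows)) {
            if (!(ctx %in% .BASES))
                stop("invalid table: unknown context '", ctx, "'")
            tblRows[[ctx]] <- toupper(as.character(rows[[ctx]]))
        }
    }
    obj <- new("RuleTable",
        scheme = if (is.null(rows)) id else "custom",
        unitLen = spec$unitLen,
        radix = spec$radix,
        maxRun = spec$maxRun,
        initiator = toupper(if (is.null(initiator)) spec$initiator else initiator),
        guard = if (is.null(guard)) spec$guard else isTRUE(guard),
        rows = tblRows)
    msg <- .validRuleTable(obj)
    if (!isTRUE(msg))
        stop("invalid table: ", paste(msg, collapse = "; "))
    obj
}

#' Read and write rule tables as JSON
#'
#' Bit-exact serialisation of a [RuleTable] in the dialect
#' `{scheme, unit_len, radix, max_run, initiator, guard, rows: {context:
#' [unit per digit]}}`. An infinite `max_run` is stored as the string
#' `"Inf"`.
#'
#' @param table a [RuleTable].
#' @param path file path.
#' @return `readRuleTableJSON` returns a validated [RuleTable];
#'   `writeRuleTableJSON` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeRuleTableJSON(buildRuleTable("R0-B3"), f)
#' readRuleTableJSON(f)
#' @export
writeRuleTableJSON <- function(table, path) {
    stopifnot(is(table, "RuleTable"))
    obj <- list(
        scheme = table@scheme,
        unit_len = table@unitLen,
        radix = table@radix,
        max_run = if (is.finite(table@maxRun)) table@maxRun else "Inf",
        initiator = table@initiator,
        guard = table@guard,
        rows = table@rows)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeRuleTableJSON
#' @export
readRuleTableJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    maxRun <- obj$max_run
    maxRun <- if (is.character(maxRun)) Inf else as.numeric(maxRun)
    tbl <- new("RuleTable",
        scheme = as.character(obj$scheme),
        unitLen = as.integer(obj$unit_len),
        radix = as.integer(obj$radix),
        maxRun = maxRun,
        initiator = as.character(obj$initiator),
        guard = isTRUE(obj$guard),
        rows = lapply(obj$rows, as.character))
    msg <- .validRuleTable(tbl)
    if (!isTRUE(msg))
        stop("invalid table: ", paste(msg, collapse = "; "))
    tbl
}
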