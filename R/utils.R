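## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state. seed = NULL leaves the current stream untouched.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a child seed for pipeline stage `k`, kept inside 32-bit range.
.childSeed <- function(seed, k) {
    if (is.null(seed)) return(NULL)
    (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

## Clamp scores into [eps, 1 - eps] so the logit is finite.
.clampUnit <- function(x, eps = 1e-6) {
    pmin(pmax(x, eps), 1 - eps)
}

## Format numbers for TSV output with enough digits to round-trip doubles
## exactly; integers and NA print plainly.
.fmtNum <- function(x) {
    out <- character(length(x))
    out[is.na(x)] <- "NA"
    ok <- !is.na(x)
    whole <- ok & (x == round(x)) & abs(x) < 1e15
    out[whole] <- sprintf("%.0f", x[whole])
    rest <- ok & !whole
    out[rest] <- sprintf("%.17g", x[rest])
    out
}

## Write a data.frame as a plain TSV (deterministic bytes: fixed number
## formatting, "NA" for missing, "\n" endings).
.writeTsv <- function(df, path) {
    cols <- lapply(df, function(col) {
        if (is.numeric(col)) .fmtNum(col)
        else if (is.logical(col)) ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
        else ifelse(is.na(col), "NA", as.character(col))
    })
    lines <- c(paste(names(df), collapse = "\t"),
               do.call(paste, c(cols, sep = "\t")))
    writeLines(lines, path)
    invisible(path)
}
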