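# Independent oracles used to cross-check the recursive scorer and the
# Mann-Whitney implementation. These deliberately share no code with the
# package internals: alternatives are handled by exhaustively expanding
# every OR into each of its branches (no max inside the evaluator), and
# the exact rank-test p-value is obtained by enumerating group assignments.

# all OR-free expansions of an expression node (list of trees)
oracleExpandOr <- function(node) {
    switch(node$kind,
        ATOM = ,
        WILDCARD = list(node),
        OPTIONAL = lapply(oracleExpandOr(node$child), function(c)
            list(kind = "OPTIONAL", child = c)),
        OR = do.call(c, lapply(node$children, oracleExpandOr)),
        AND = {
            expansions <- lapply(node$children, oracleExpandOr)
            combos <- expand.grid(lapply(expansions, seq_along))
            lapply(seq_len(nrow(combos)), function(r) {
                kids <- lapply(seq_along(expansions), function(j)
                    expansions[[j]][[combos[r, j]]])
                list(kind = "AND", style = node$style, children = kids)
            })
        })
}

# proportional evaluation of an OR-free tree; NA marks vacuous
# (all-optional) groups, excluded from the enclosing mean
oracleEvalOrFree <- function(node, kos) {
    switch(node$kind,
        ATOM = if (node$ko %in% kos) 1 else 0,
        WILDCARD = 1,
        OPTIONAL = NA_real_,
        AND = {
            v <- vapply(node$children, oracleEvalOrFree, numeric(1), kos)
            v <- v[!is.na(v)]
            if (length(v) == 0) NA_real_ else mean(v)
        },
        stop("OR in supposedly OR-free tree"))
}

# brute-force module score: per step, max over all OR-branch expansions
oracleModuleScore <- function(module, kos) {
    kos <- unique(toupper(kos))
    stepScores <- vapply(moduleSteps(module), function(step) {
        v <- vapply(oracleExpandOr(step), oracleEvalOrFree, numeric(1),
                    kos)
        v <- v[!is.na(v)]
        if (length(v) == 0) NA_real_ else max(v)
    }, numeric(1))
    stepScores <- stepScores[!is.na(stepScores)]
    if (length(stepScores) == 0) 0 else mean(stepScores)
}

# flat fraction-present score for a step expansion whose components are all
# atoms/wildcards (where proportional and flat semantics coincide)
oracleFlatFraction <- function(expansion, kos) {
    comps <- if (expansion$kind == "AND") expansion$children
             else list(expansion)
    req <- Filter(function(c) c$kind != "OPTIONAL", comps)
    if (length(req) == 0) return(NA_real_)
    if (!all(vapply(req, function(c) c$kind %in% c("ATOM", "WILDCARD"),
                    logical(1))))
        return(NA_real_)    # nested group: flat semantics do not apply
    mean(vapply(req, function(c)
        if (c$kind == "WILDCARD") 1 else as.numeric(c$ko %in% kos),
        numeric(1)))
}

# exact two-tailed Mann-Whitney p by enumerating all group assignments
oracleExactMwu <- function(a, b) {
    pooled <- c(a, b)
    stopifnot(!anyDuplicated(pooled))
    na <- length(a); nb <- length(b)
    uStat <- function(idx) {
        x <- pooled[idx]; y <- pooled[-idx]
        sum(outer(x, y, ">"))
    }
    uObs <- uStat(seq_len(na))
    all <- utils::combn(na + nb, na)
    us <- apply(all, 2, uStat)
    pLo <- mean(us <= uObs)
    pHi <- mean(us >= uObs)
    min(1, 2 * min(pLo, pHi))
}

# all KO subsets of a vector (list of character vectors)
allSubsets <- function(kos) {
    n <- length(kos)
    lapply(0:(2^n - 1), function(mask)
        kos[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
}
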