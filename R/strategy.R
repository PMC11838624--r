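#' Enumerate all observation histories of a given length
#'
#' Histories are bit strings written oldest bit first, most recent bit
#' last, e.g. `"01"` means the previous observation was 0 and the most
#' recent was 1. Returned in lexicographic order, which doubles as the
#' canonical table order everywhere in the package.
#'
#' @param n Window length (depth), `n >= 0`. For `n = 0` the single empty
#'   history `""` is returned.
#' @return Character vector of length `2^n`.
#' @export
all_histories <- local({
  cache <- list()
  function(n) {
    stopifnot(length(n) == 1, n >= 0, n == as.integer(n))
    if (n == 0) return("")
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      grid <- expand.grid(rep(list(c("0", "1")), n), stringsAsFactors = FALSE)
      cache[[key]] <<- sort(do.call(paste0, rev(grid)))
    }
    cache[[key]]
  }
})

#' Intervention strategy (decision table)
#'
#' A depth-`n` strategy maps every length-`n` observation history to an
#' action: 1 = intervene, 0 = do not. For `n = 0` the table holds the
#' single unconditional action.
#'
#' @param n Surveillance depth (window length), `n >= 0`.
#' @param table Actions in \{0, 1\}. Either an unnamed vector of length
#'   `2^n` in the lexicographic history order of [all_histories()], or a
#'   vector fully named by history strings (oldest bit first).
#' @return An object of class `strategy`: named integer vector of actions
#'   with attribute `n`.
#' @examples
#' strategy(1, c(0, 1))                    # intervene iff last bit is 1
#' strategy(2, c("11" = 1, "00" = 0, "01" = 0, "10" = 0))
#' @export
strategy <- function(n, table) {
  stopifnot(length(n) == 1, n >= 0, n == as.integer(n))
  n <- as.integer(n)
  hists <- all_histories(n)
  tab <- unlist(table)
  if (length(tab) != 2^n) {
    stop(sprintf("table must have %d entries for n = %d, got %d",
                 2^n, n, length(tab)), call. = FALSE)
  }
  if (!all(tab %in% c(0, 1))) {
    stop("table entries must be 0 or 1", call. = FALSE)
  }
  if (!is.null(names(tab)) && any(nzchar(names(tab)) | n == 0)) {
    if (!setequal(names(tab), hists)) {
      stop("table names must be exactly the length-n bit histories",
           call. = FALSE)
    }
    tab <- tab[hists]
  } else {
    names(tab) <- hists
  }
  structure(as.integer(tab), names = hists, n = n, class = "strategy")
}

#' @rdname strategy
#' @param x Object to test or print.
#' @export
is_strategy <- function(x) inherits(x, "strategy")

#' Degenerate strategies
#'
#' `strategy_never(n)` never intervenes; `strategy_always(n)` always does.
#' At depth 0 these are the two no-surveillance baselines.
#'
#' @param n Surveillance depth.
#' @return A [strategy()].
#' @export
strategy_never <- function(n = 0) strategy(n, rep(0L, 2^n))

#' @rdname strategy_never
#' @export
strategy_always <- function(n = 0) strategy(n, rep(1L, 2^n))

#' Depth of a strategy
#' @param strat A [strategy()].
#' @return Integer window length `n`.
#' @export
strategy_depth <- function(strat) {
  stopifnot(is_strategy(strat))
  attr(strat, "n")
}

#' Compact strategy label
#'
#' Depth-0 strategies are labelled `"never"`/`"always"`; otherwise
#' `"n=<depth>:<actions>"` with actions in lexicographic history order,
#' e.g. `"n=1:01"` for intervene-iff-last-bit-is-1.
#'
#' @param strat A [strategy()].
#' @return A single string.
#' @export
strategy_label <- function(strat) {
  stopifnot(is_strategy(strat))
  n <- strategy_depth(strat)
  bits <- paste(unclass(strat), collapse = "")
  if (n == 0) return(if (bits == "1") "always" else "never")
  sprintf("n=%d:%s", n, bits)
}

#' Parse a strategy from its compact label
#'
#' Inverse of [strategy_label()]; also accepts `"never"` and `"always"`.
#'
#' @param label String such as `"n=2:0001"`.
#' @return A [strategy()].
#' @export
parse_strategy <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  if (label == "never") return(strategy_never(0))
  if (label == "always") return(strategy_always(0))
  m <- regmatches(label, regexec("^n=([0-9]+):([01]+)$", label))[[1]]
  if (length(m) != 3) {
    stop(sprintf("cannot parse strategy label '%s'", label), call. = FALSE)
  }
  n <- as.integer(m[2])
  bits <- as.integer(strsplit(m[3], "")[[1]])
  strategy(n, bits)
}

#' Read / write a strategy as JSON
#'
#' Schema: `{"n": <int>, "table": {"<history>": 0 or 1, ...}}` with history
#' strings oldest bit first.
#'
#' @param path File path.
#' @param strat A [strategy()].
#' @return `read_strategy` returns a [strategy()]; `write_strategy`
#'   returns `path` invisibly.
#' @export
read_strategy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$n) || is.null(obj$table)) {
    stop(sprintf("strategy file '%s' must have fields 'n' and 'table'", path),
         call. = FALSE)
  }
  strategy(obj$n, unlist(obj$table))
}

#' @rdname read_strategy
#' @export
write_strategy <- function(strat, path) {
  stopifnot(is_strategy(strat))
  obj <- list(n = strategy_depth(strat), table = as.list(unclass(strat)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy depth n = %d>  %s\n", strategy_depth(x),
              strategy_label(x)))
  if (strategy_depth(x) > 0) {
    df <- data.frame(history = names(x), action = as.integer(x),
                     row.names = NULL)
    print(df, row.names = FALSE)
  } else {
    cat(sprintf("  unconditional action: %d\n", as.integer(x[1])))
  }
  invisible(x)
}

#' @export
format.strategy <- function(x, ...) strategy_label(x)
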