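`%||%` <- function(a, b) if (is.null(a)) b else a

gf_error <- function(msg, class) {
  stop(structure(
    class = c(class, "gf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

gf_validation_error <- function(msg) gf_error(msg, "gf_validation_error")
gf_parse_error <- function(msg) gf_error(msg, "gf_parse_error")
gf_io_error <- function(msg) gf_error(msg, "gf_io_error")

# Inclusive-comparison guard for ratio thresholds: group ratios are quotients
# of small integers but user thresholds arrive as decimal text, so equality
# at a boundary (e.g. 9/10 vs 0.90) must not be lost to representation error.
GF_EPS <- 1e-9

# Canonical, field-order-independent serialization used as cache key.
# Names are sorted recursively and scalars unboxed, so two semantically
# identical queries serialize identically regardless of construction order.
canonical_json <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm)) v <- v[order(nm)]
      lapply(v, canon)
    } else if (is.null(v)) {
      NULL
    } else {
      v
    }
  }
  as.character(jsonlite::toJSON(canon(x), auto_unbox = TRUE, null = "null",
                                digits = NA))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

open_text_sink <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

is_gz <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}
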