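# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# C-locale (radix) sort so output files are byte-stable across locales
csort <- function(x) sort(x, method = "radix")

# locale-independent "a > b" for canonicalizing unordered gene pairs
str_gt <- function(a, b) {
  lev <- csort(unique(c(a, b)))
  match(a, lev) > match(b, lev)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_tn <- function(...) stop(..., call. = FALSE)

comma_join <- function(x) paste(csort(unique(x[!is.na(x) & nzchar(x)])), collapse = ",")

# file stem used as default resource name
path_stem <- function(path) tools::file_path_sans_ext(basename(path))
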