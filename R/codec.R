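#' Define a PPM codespace
#'
#' A codemap fixes how inter-ping intervals carry a tag identity: a sync
#' interval anchoring the packet, `n_data_intervals` data intervals each
#' quantized to one of `n_symbols` evenly spaced bins
#' (`base_interval_s + symbol * step_s`), the last data symbol acting as a
#' modular checksum, and an acceptance radius `max_residual_s` around each bin
#' center. Vendors' real codespaces are proprietary and rotate over time, so
#' codemaps are user-supplied configuration; the package ships a documented
#' example codespace (see [default_codemap()]).
#'
#' @param name codespace label.
#' @param sync_interval_s sync (first) interval, seconds.
#' @param n_data_intervals number of data intervals after the sync interval.
#' @param base_interval_s interval encoding symbol 0, seconds.
#' @param step_s interval increment per symbol, seconds.
#' @param n_symbols symbols per interval (0 .. n_symbols-1).
#' @param checksum_rule only `"sum_mod"` is defined: the last symbol must
#'   equal the sum of the preceding symbols modulo `n_symbols`.
#' @param max_residual_s quantization acceptance radius; must satisfy
#'   `step_s > 2 * max_residual_s` so bins cannot overlap.
#' @return A classed list (`ppm_codemap`).
#' @export
ppm_codemap <- function(name, sync_interval_s, n_data_intervals,
                        base_interval_s, step_s, n_symbols,
                        checksum_rule = "sum_mod", max_residual_s) {
  if (!identical(checksum_rule, "sum_mod")) {
    stop("unknown checksum_rule '", checksum_rule,
         "': only 'sum_mod' is defined", call. = FALSE)
  }
  if (step_s <= 2 * max_residual_s) {
    stop("step_s must exceed 2 * max_residual_s, otherwise adjacent ",
         "interval bins overlap under the acceptance radius", call. = FALSE)
  }
  if (n_symbols < 2 || n_data_intervals < 2) {
    stop("need n_symbols >= 2 and n_data_intervals >= 2", call. = FALSE)
  }
  structure(list(name = name, sync_interval_s = sync_interval_s,
                 n_data_intervals = as.integer(n_data_intervals),
                 base_interval_s = base_interval_s, step_s = step_s,
                 n_symbols = as.integer(n_symbols),
                 checksum_rule = checksum_rule,
                 max_residual_s = max_residual_s),
            class = "ppm_codemap")
}

#' The example codespace shipped with the package
#'
#' 0.280 s sync, 6 data intervals of 8 symbols (0.455 s + symbol x 8 ms), the
#' last a modular checksum, acceptance radius step/3. Full packets span
#' 3.010–3.346 s, inside the 3–3.5 s envelope of real 69 kHz tags. The ID
#' space holds `8^5 = 32768` tags. This is an illustrative codespace, not a
#' vendor's.
#'
#' @return A [ppm_codemap()].
#' @export
default_codemap <- function() {
  ppm_codemap(name = "example-69khz-v1", sync_interval_s = 0.280,
              n_data_intervals = 6L, base_interval_s = 0.455,
              step_s = 0.008, n_symbols = 8L,
              checksum_rule = "sum_mod", max_residual_s = 0.008 / 3)
}

#' Number of distinct tag IDs a codemap can carry
#' @param map a [ppm_codemap()].
#' @return `n_symbols ^ (n_data_intervals - 1)` (last interval is checksum).
#' @export
codemap_id_space <- function(map) {
  map$n_symbols^(map$n_data_intervals - 1L)
}

#' Encode a tag ID as PPM intervals
#'
#' Expresses the ID base-`n_symbols` over the data positions
#' (most-significant first), appends the modular checksum symbol, maps each
#' symbol to its interval and prepends the sync interval.
#'
#' @param tag_id non-negative integer below [codemap_id_space()].
#' @param map a [ppm_codemap()].
#' @return Numeric vector of `1 + n_data_intervals` intervals (seconds).
#' @export
#' @examples
#' encode_tag(0)    # all symbols 0: 0.280 then six 0.455 s intervals
#' encode_tag(668)  # digits 0,1,2,3,4 base 8, checksum 2
encode_tag <- function(tag_id, map = default_codemap()) {
  n_data <- map$n_data_intervals - 1L
  space <- map$n_symbols^n_data
  if (tag_id < 0 || tag_id >= space || tag_id != floor(tag_id)) {
    stop("tag_id must be an integer in [0, ", space - 1, "]", call. = FALSE)
  }
  digits <- integer(n_data)
  rem <- tag_id
  for (k in n_data:1) {
    digits[k] <- rem %% map$n_symbols
    rem <- rem %/% map$n_symbols
  }
  syms <- c(digits, sum(digits) %% map$n_symbols)
  c(map$sync_interval_s, map$base_interval_s + syms * map$step_s)
}

#' Decode PPM intervals to a tag ID
#'
#' Software stand-in for a hardware deck-box decoder. The sync interval must
#' fall within `max_residual_s` of the codemap's; each data interval is
#' quantized to the nearest symbol bin and rejected if the residual exceeds
#' the acceptance radius; the checksum is verified. Within the acceptance
#' radius the decoder never silently mis-decodes: it either returns the
#' encoded ID or a structured rejection.
#'
#' @param intervals_s the 7 (generally `1 + n_data_intervals`) positive
#'   intervals of a candidate packet, seconds.
#' @param map a [ppm_codemap()].
#' @return A list of class `ppm_decode`: `status` (`"ok"` or `"no_match"`),
#'   `tag_id` (integer or `NA`), `reason` (`NA`, `"bad_sync"`, `"off_bin"` or
#'   `"bad_checksum"`).
#' @export
decode_intervals <- function(intervals_s, map = default_codemap()) {
  no_match <- function(reason) {
    structure(list(status = "no_match", tag_id = NA_integer_,
                   reason = reason), class = "ppm_decode")
  }
  intervals_s <- as.numeric(intervals_s)
  if (length(intervals_s) != map$n_data_intervals + 1L ||
      any(intervals_s <= 0)) {
    return(no_match("bad_sync"))
  }
  if (abs(intervals_s[1] - map$sync_interval_s) > map$max_residual_s) {
    return(no_match("bad_sync"))
  }
  data <- intervals_s[-1]
  syms <- round((data - map$base_interval_s) / map$step_s)
  resid <- abs(data - (map$base_interval_s + syms * map$step_s))
  if (any(syms < 0) || any(syms >= map$n_symbols) ||
      any(resid > map$max_residual_s + 1e-12)) {
    return(no_match("off_bin"))
  }
  n_data <- map$n_data_intervals - 1L
  if (syms[map$n_data_intervals] != sum(syms[seq_len(n_data)]) %%
      map$n_symbols) {
    return(no_match("bad_checksum"))
  }
  id <- 0
  for (k in seq_len(n_data)) id <- id * map$n_symbols + syms[k]
  structure(list(status = "ok", tag_id = as.integer(id), reason = NA),
            class = "ppm_decode")
}

#' @export
print.ppm_decode <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<decode: tag %d>\n", x$tag_id))
  } else {
    cat(sprintf("<decode: no_match (%s)>\n", x$reason))
  }
  invisible(x)
}

#' Read / write codemap files
#'
#' Codemaps are plain JSON with exactly the [ppm_codemap()] fields; loading
#' validates the bin-separation invariant, so a map whose bins could overlap
#' under the acceptance radius is rejected at load time.
#'
#' @param path JSON file path.
#' @return [load_codemap()] returns a validated [ppm_codemap()];
#'   [save_codemap()] returns `path` invisibly.
#' @export
load_codemap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "sync_interval_s", "n_data_intervals", "base_interval_s",
            "step_s", "n_symbols", "checksum_rule", "max_residual_s")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("codemap '", path, "' is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ppm_codemap(name = x$name, sync_interval_s = x$sync_interval_s,
              n_data_intervals = x$n_data_intervals,
              base_interval_s = x$base_interval_s, step_s = x$step_s,
              n_symbols = x$n_symbols, checksum_rule = x$checksum_rule,
              max_residual_s = x$max_residual_s)
}

#' @rdname load_codemap
#' @param map a [ppm_codemap()].
#' @export
save_codemap <- function(map, path) {
  stopifnot(inherits(map, "ppm_codemap"))
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
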