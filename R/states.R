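#' Disability-state encoding over the nine ADL domains
#'
#' Each assessment of activities of daily living (ADL) records nine binary
#' impairment domains: bathing (B), grooming (G), dressing (D), feeding (F),
#' transferring (S), walking (W), toilet use (T), bowel continence (L) and
#' urinary continence (U). A *disability state* is one combination of impaired
#' domains, encoded as a 9-bit integer in `[0, 511]` under a fixed per-domain
#' bit weight:
#'
#' | domain | F | D | G | S | B | W | T  | L   | U   |
#' |--------|---|---|---|---|---|---|----|-----|-----|
#' | weight | 1 | 2 | 4 | 8 | 16| 32| 64 | 128 | 256 |
#'
#' The encoding is order-insensitive: `GBW`, `GWB` and `WBG` all denote the
#' state with grooming, bathing and walking impaired, code
#' `4 + 16 + 32 = 52`. Code 0 is the no-impairment state, 511 the state with
#' all nine domains impaired, and 510 all domains except feeding.
#'
#' @param impairments character vector of domain letters (a subset of
#'   `adl_domains()`); duplicates are ignored.
#' @return `encode_state()` returns a single integer code in `[0, 511]`.
#' @examples
#' encode_state(c("G", "B", "W"))   # 52
#' encode_state(character(0))       # 0
#' decode_state(20)                 # c("G", "B")
#' state_severity(511)              # 9
#' @seealso [decode_state()], [state_severity()]
#' @export
encode_state <- function(impairments) {
  impairments <- unique(as.character(impairments))
  if (length(impairments) == 0L) return(0L)
  unknown <- setdiff(impairments, adl_domains())
  if (length(unknown) > 0L) {
    stop("unknown ADL domain token(s): ", paste(unknown, collapse = ", "))
  }
  sum(.adl_bits[impairments])
}

#' @rdname encode_state
#' @param code integer state code(s) in `[0, 511]`.
#' @return `decode_state()` returns the character vector of impaired domains
#'   (in bit-weight order) for a single code.
#' @export
decode_state <- function(code) {
  code <- .check_code(code)
  if (length(code) != 1L) stop("decode_state() takes a single code")
  doms <- names(.adl_bits)[bitwAnd(code, .adl_bits) > 0L]
  doms
}

#' @rdname encode_state
#' @return `state_severity()` returns, per code, the number of impaired
#'   domains (0..9), the state attribute used for severity-based substitution
#'   costs.
#' @export
state_severity <- function(code) {
  code <- .check_code(code)
  vapply(code, function(cd) sum(bitwAnd(cd, .adl_bits) > 0L), integer(1))
}

#' @rdname encode_state
#' @return `adl_domains()` returns the nine domain letters in bit-weight order.
#' @export
adl_domains <- function() names(.adl_bits)

#' @rdname encode_state
#' @return `state_label()` returns a compact label such as `"GBW"` (domains in
#'   bit-weight order), or `"O"` for the no-impairment state.
#' @export
state_label <- function(code) {
  code <- .check_code(code)
  vapply(code, function(cd) {
    if (cd == 0L) return("O")
    paste(names(.adl_bits)[bitwAnd(cd, .adl_bits) > 0L], collapse = "")
  }, character(1))
}

# Fixed bit-weight map. F, G, B, W weights are pinned by the published example
# codes (GBW=52, GB=20, W=32, 510=all-but-F); the remaining five follow the
# listing order of the domains.
.adl_bits <- c(F = 1L, D = 2L, G = 4L, S = 8L, B = 16L, W = 32L,
               T = 64L, L = 128L, U = 256L)

.check_code <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L) || any(code > 511L)) {
    stop("state codes must be integers in [0, 511]")
  }
  code
}
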