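#' The nine TCM constitution labels
#'
#' Fixed controlled vocabulary for the constitution role: balanced (BC),
#' yang-deficiency (YADC), yin-deficiency (YIDC), qi-deficiency (QDC),
#' qi-stagnation (QSC), phlegm-dampness (PDC), dampness-heat (DHC),
#' blood stasis (BSC) and inherited special (ISC).
#'
#' @format Character vector of length 9.
#' @export
constitution_labels <- c("BC", "YADC", "YIDC", "QDC", "QSC",
                         "PDC", "DHC", "BSC", "ISC")

#' Item roles
#'
#' Every item carried by a transaction is a typed categorical token; the role
#' is explicit (never inferred from the token) so that, e.g., a drug and a
#' symptom with the same name never collide.
#'
#' @format Character vector of length 5.
#' @export
item_roles <- c("symptom", "constitution", "regimen", "disease", "drug")

# collapse runs of whitespace, trim, casefold per role
normalize_token <- function(token, role) {
  token <- gsub("\\s+", " ", trimws(as.character(token)))
  if (role == "constitution") toupper(token) else tolower(token)
}

validate_tokens <- function(tokens, role, what = role) {
  if (!length(tokens)) return(character(0))
  tokens <- vapply(tokens, normalize_token, character(1), role = role,
                   USE.NAMES = FALSE)
  if (any(!nzchar(tokens)))
    stop("empty ", what, " token after whitespace normalization",
         call. = FALSE)
  if (any(grepl("[|:]", tokens)))
    stop(what, " tokens must not contain '|' or ':'", call. = FALSE)
  if (role == "constitution") {
    bad <- setdiff(tokens, constitution_labels)
    if (length(bad))
      stop("unknown constitution label(s): ", paste(bad, collapse = ", "),
           "; must be one of ", paste(constitution_labels, collapse = ", "),
           call. = FALSE)
  }
  unique(tokens)
}

#' Construct qualified items
#'
#' An item is a role-qualified token serialized as `"role:token"`. Tokens are
#' whitespace-normalized and case-folded (lower case, except constitution
#' labels which normalize to upper case and must belong to
#' [constitution_labels]).
#'
#' @param token Character vector of raw tokens.
#' @param role A single role from [item_roles].
#' @return Character vector of qualified items.
#' @examples
#' tcm_item(c("Easy  Fatigue", "pale face"), "symptom")
#' tcm_item("pdc", "constitution")
#' @export
tcm_item <- function(token, role = item_roles) {
  role <- match.arg(role)
  tokens <- if (length(token)) {
    vapply(token, normalize_token, character(1), role = role,
           USE.NAMES = FALSE)
  } else character(0)
  if (any(!nzchar(tokens)))
    stop("empty token after whitespace normalization", call. = FALSE)
  if (any(grepl("[|:]", tokens)))
    stop("tokens must not contain '|' or ':'", call. = FALSE)
  if (role == "constitution") {
    bad <- setdiff(tokens, constitution_labels)
    if (length(bad))
      stop("unknown constitution label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!length(tokens)) return(character(0))
  paste0(role, ":", tokens)
}

#' @rdname tcm_item
#' @param item Character vector of qualified items (`"role:token"`).
#' @export
item_role <- function(item) sub(":.*$", "", item)

#' @rdname tcm_item
#' @export
item_token <- function(item) sub("^[^:]*:", "", item)

# canonical itemset key: items sorted in C locale, joined by "|"
itemset_key <- function(items) {
  paste(sort(items, method = "radix"), collapse = "|")
}

key_items <- function(key) strsplit(key, "|", fixed = TRUE)

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# 32-bit FNV-1a over a character vector; provenance checksum for rule bases
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor into the low byte (h exceeds .Machine$integer.max, so stay in doubles)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + (hi * p %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
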