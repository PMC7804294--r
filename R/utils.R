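# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# Canonical residue key: chain + author residue number + insertion code.
.resKey <- function(chain, resno, insert = NULL) {
  ins <- if (is.null(insert)) "" else ifelse(is.na(insert) | insert == "", "", insert)
  paste0(chain, ":", resno, ins)
}

# Canonical unordered node-pair key ("a|b", lexicographic).
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Evolutionary status labels, in the canonical orientation used for
# status-pair labels: transition-acquired extension statuses first, then
# protein statuses, functional sites last.
.STATUS_RANK <- c(Ue = 1, Ua = 2, Ub = 3, Ae = 4,
                  U = 5, A = 6, B = 7, E = 8, funct = 9)

#' @noRd
.statusPair <- function(sa, sb) {
  ra <- .STATUS_RANK[sa]
  rb <- .STATUS_RANK[sb]
  if (any(is.na(ra)) || any(is.na(rb))) {
    bad <- unique(c(sa[is.na(ra)], sb[is.na(rb)]))
    stop("unknown evolutionary status label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  swap <- rb < ra | (rb == ra & sb < sa)
  first <- ifelse(swap, sb, sa)
  second <- ifelse(swap, sa, sb)
  paste(first, second, sep = "-")
}

.FUNCTIONAL_SITES <- c("PTC", "tunnel", "mRNA", "tRNA_A", "tRNA_P", "tRNA_E")

.CONTACT_TYPES <- c("ext_ext", "ext_G", "G_G", "ext_funct", "G_funct")

# Subunit from unified nomenclature names (uS3, eL15, bL20 ...) or site ids.
.subunitOf <- function(node_id) {
  out <- rep(NA_character_, length(node_id))
  out[grepl("^[ueb]S[0-9]+$", node_id)] <- "SSU"
  out[grepl("^[ueb]L[0-9]+$", node_id)] <- "LSU"
  out[node_id %in% c("mRNA", "tRNA_A", "tRNA_P", "tRNA_E")] <- "SSU"
  out[node_id %in% c("PTC", "tunnel")] <- "LSU"
  out
}
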