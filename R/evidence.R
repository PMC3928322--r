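# Evidence-code policies.

# Closed set of GO evidence codes known to the toolkit.
GO_EVIDENCE_CODES <- c(
  # experimental
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
  # high-throughput experimental
  "HTP", "HDA", "HMP", "HGI", "HEP",
  # computational analysis
  "ISS", "ISO", "ISA", "ISM", "IGC", "IBA", "IBD", "IKR", "IRD", "RCA",
  # author / curator statements
  "TAS", "NAS", "IC", "ND",
  # automatic
  "IEA"
)

# ISS and its children.
ISS_FAMILY <- c("ISS", "ISO", "ISA", "ISM")

#' Construct an evidence-code policy
#'
#' A policy is a whitelist of accepted codes plus a set of blacklist families;
#' a family is a code together with its child codes (currently only the ISS
#' family, ISS/ISO/ISA/ISM, is expanded). A record passes the policy when its
#' code is whitelisted and not in any expanded blacklist family. The whitelist
#' and the expanded blacklist must be disjoint.
#'
#' @param whitelist character vector of accepted evidence codes.
#' @param blacklist_families character vector of codes whose family is
#'   rejected.
#' @return an `evidence_policy` object.
#' @seealso [transfer_policy()], [geneset_policy()]
#' @export
evidence_policy <- function(whitelist, blacklist_families = character()) {
  unknown <- setdiff(c(whitelist, blacklist_families), GO_EVIDENCE_CODES)
  if (length(unknown)) {
    abort(sprintf("unknown evidence code(s): %s", paste(unknown, collapse = ", ")))
  }
  expanded <- expand_families(blacklist_families)
  if (length(intersect(whitelist, expanded))) {
    abort("whitelist and expanded blacklist overlap")
  }
  structure(
    list(whitelist = unique(whitelist), blacklist = expanded),
    class = "evidence_policy"
  )
}

#' @rdname evidence_policy
#' @param codes codes to expand into families.
#' @export
expand_families <- function(codes) {
  out <- codes
  if ("ISS" %in% codes) out <- c(out, ISS_FAMILY)
  unique(out)
}

#' Transfer policy: experimental evidence only
#'
#' The policy gating cross-species annotation transfer: only experimentally
#' supported annotations (EXP, IDA, IPI, IMP, IGI, IEP) are eligible.
#' Computationally derived codes — ISS and its children — are rejected to
#' avoid re-generalizing annotations that may themselves have come from
#' orthology, and automatically assigned (IEA), author-statement (TAS, NAS)
#' and curator-statement (IC, ND) codes are rejected as well.
#'
#' @return an `evidence_policy`.
#' @export
transfer_policy <- function() {
  evidence_policy(
    whitelist = c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP"),
    blacklist_families = c("ISS", "IEA", "TAS", "NAS", "IC", "ND")
  )
}

#' Gene-set policy: evidence codes admitted into gene sets
#'
#' Mirrors the evidence filter used by GO-derived gene-set collections such as
#' MSigDB C5: IDA, IPI, IMP, IGI, IEP, ISS and TAS. Note that ortholog-derived
#' records bypass this policy inside [build_collection()]: they are always
#' admitted regardless of their (mouse) evidence code.
#'
#' @return an `evidence_policy`.
#' @export
geneset_policy <- function() {
  evidence_policy(whitelist = c("IDA", "IPI", "IMP", "IGI", "IEP", "ISS", "TAS"))
}

#' @export
print.evidence_policy <- function(x, ...) {
  cat(sprintf(
    "<evidence_policy> whitelist: %s; blacklist: %s\n",
    paste(x$whitelist, collapse = ","),
    if (length(x$blacklist)) paste(x$blacklist, collapse = ",") else "(none)"
  ))
  invisible(x)
}
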