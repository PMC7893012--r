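#' Atlas specification
#'
#' An atlas maps ROI indices to names and to one of the seven canonical
#' intrinsic-connectivity networks (Visual, Somatomotor, DorsalAttention,
#' VentralAttention, Limbic, Frontoparietal, Default).  Two parcellation
#' granularities are supported: the 7-network functional parcellation
#' (`yeo7`, one node per network) and the 90-region anatomical parcellation
#' (`aal90`, regions grouped into the same seven networks).
#'
#' @param name atlas identifier, `"yeo7"` or `"aal90"`.
#' @param roi_names character vector of ROI labels.
#' @param network_of character vector, same length, giving each ROI's network.
#' @return an object of class `atlas_spec`.
#' @export
atlas_spec <- function(name, roi_names, network_of) {
  stopifnot(length(roi_names) == length(network_of),
            !anyDuplicated(roi_names))
  structure(
    list(name = name, n_rois = length(roi_names),
         roi_names = roi_names, network_of = network_of),
    class = "atlas_spec"
  )
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("<atlas_spec> %s: %d ROIs, %d networks\n",
              x$name, x$n_rois, length(unique(x$network_of))))
  invisible(x)
}

#' The canonical seven network labels
#' @export
yeo7_networks <- function() {
  c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
    "Limbic", "Frontoparietal", "Default")
}

#' Seven-network functional atlas (one node per network)
#' @export
yeo7_atlas <- function() {
  nets <- yeo7_networks()
  atlas_spec("yeo7", roi_names = nets, network_of = nets)
}

#' 90-region anatomical atlas with a default 7-network grouping
#'
#' Region names follow the standard 90-region anatomical labelling
#' (cerebrum only, left/right interleaved).  The region-to-network
#' assignment is a convenience default shipped as an editable table
#' (`inst/extdata/aal90_networks.tsv`); pass `mapping_file` to use a
#' different grouping.
#'
#' @param mapping_file path to a two-column TSV (`region`, `network`);
#'   default uses the packaged table.
#' @export
aal90_atlas <- function(mapping_file = NULL) {
  if (is.null(mapping_file)) {
    mapping_file <- system.file("extdata", "aal90_networks.tsv",
                                package = "connstate", mustWork = TRUE)
  }
  tab <- utils::read.delim(mapping_file, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "network") %in% names(tab)))
  bad <- setdiff(unique(tab$network), yeo7_networks())
  if (length(bad)) {
    stop("unknown network label(s) in mapping: ", paste(bad, collapse = ", "))
  }
  atlas_spec("aal90", roi_names = tab$region, network_of = tab$network)
}

#' Look up an atlas by identifier
#' @param name `"yeo7"` or `"aal90"`.
#' @export
get_atlas <- function(name) {
  switch(name,
    yeo7 = yeo7_atlas(),
    aal90 = aal90_atlas(),
    stop("unknown atlas: ", name)
  )
}

#' Edges between two networks
#'
#' Returns the rows of [edge_index()] whose endpoints lie in the two given
#' networks (order-free).  Used to place planted effects and to read out
#' between-network components.
#'
#' @param atlas an `atlas_spec`.
#' @param net_a,net_b network labels.
#' @return integer matrix of (i, j) node pairs, i < j.
#' @export
network_pair_edges <- function(atlas, net_a, net_b) {
  idx <- edge_index(atlas$n_rois)
  ni <- atlas$network_of[idx[, "i"]]
  nj <- atlas$network_of[idx[, "j"]]
  keep <- (ni == net_a & nj == net_b) | (ni == net_b & nj == net_a)
  idx[keep, , drop = FALSE]
}
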