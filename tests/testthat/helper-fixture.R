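# Shared synthetic study conditions: 200-cluster database in 20 families,
# implants at divergence 0.2 spanning all event kinds and both strands.
# Built lazily and cached for the session so several test files can share
# one search run.

default_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_protein_db(seed = 101L)
    cache
  }
})

default_implants <- function(db) {
  # one source family per implant so signals are independent
  src <- db$families$cluster_id[!duplicated(db$families$family_id)]
  rbind(
    implant_spec("intact_gene", src[1], frame = 1L),
    implant_spec("intact_gene", src[2], frame = 2L),
    implant_spec("intact_gene", src[3], frame = 3L),
    implant_spec("intact_gene", src[4], frame = 4L),
    implant_spec("intact_gene", src[5], frame = 5L),
    implant_spec("intact_gene", src[6], frame = 6L),
    implant_spec("pseudogene_stops", src[7], n_stops = 3L, frame = 1L),
    implant_spec("pseudogene_stops", src[8], n_stops = 2L, frame = 5L),
    implant_spec("terminal_subtraction", src[9], frame = 2L),
    implant_spec("foreign_fragment", src[10], frame = 4L),
    implant_spec("pseudogene_frameshift", src[11], n_frameshifts = 1L,
                 frame = 3L))
}

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      db <- default_db()
      cache <<- c(list(db = db),
                  generate_genome_with_implants(default_implants(db), db,
                                                seed = 202L))
    }
    cache
  }
})

# cross-file scratch space (e.g. the calibrated cutoff, reused by the
# planted-signal test after the null-control test computes it)
fixture_state <- new.env(parent = emptyenv())

# scan of the default fixture's regions with default scheme/config,
# cached: used by end-to-end, null-control and acceptance tests
default_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fix <- default_fixture()
      regions <- extract_inter_exon_regions(fix$annotation, fix$genome)
      scheme <- scoring_scheme()
      config <- search_config()
      per_region <- lapply(seq_len(nrow(regions)), function(i) {
        tr <- six_frame_translate(regions[i, ])
        hits <- search_hits(tr, fix$db$proteins, scheme, config)
        profiles <- lapply(tr, function(t)
          accumulate_profile(hits[hits$query_id == t$frame_id, ,
                                  drop = FALSE], t))
        list(region = regions[i, ], translations = tr, hits = hits,
             profiles = profiles)
      })
      cache <<- list(regions = regions, scheme = scheme, config = config,
                     per_region = per_region)
    }
    cache
  }
})
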