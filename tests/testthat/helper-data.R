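# Fixture builders shared across test files. All synthetic, built in code.

library(data.table)

make_events <- function(press, release = press + 80, key_class = "char",
                        participant_id = "P1") {
  ev <- data.table::data.table(press_ts = press, release_ts = release,
                               key_class = rep(key_class,
                                               length.out = length(press)),
                               participant_id = participant_id)
  data.table::setorder(ev, press_ts, release_ts)
  ev[]
}

# sessions + events in the preprocessed shape expected by extract_features
as_pre <- function(events, gap_ms = 8000) {
  filter_burst_sessions(segment_sessions(events, gap_ms))
}

.fixtures <- new.env(parent = emptyenv())

# small synthetic study reused by structure-level tests (~5 s to build)
tiny_study <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- generator_config(n_per_group = c("<30" = 2, "30s" = 2,
                                            "40s" = 2, "50s" = 2),
                            n_weeks = 3, seed = 7)
    .fixtures$tiny <- simulate_study(cfg)
  }
  .fixtures$tiny
}
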