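# shared fixtures built in code

clean_ds <- function(scenario = "long_trap", seed = 1, n_events = 6,
                     n_taxa = 2) {
  generate_scenario(scenario_spec(scenario, n_events = n_events,
                                  n_taxa = n_taxa, seed = seed))
}

write_lines_csv <- function(lines, path = withr::local_tempfile(fileext = ".csv",
                                                                .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

record_multiset <- function(records) {
  sort(paste(canonical_key(records), records$value))
}

expect_rule <- function(report, rule_id) {
  expect_true(rule_id %in% report$findings$rule_id,
              label = paste0("report contains ", rule_id))
}
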