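# Column schema for cosmoskit plain-text data files.

intervals_csv:
  description: >
    Interval table written by write_intervals(). Line 1 is the format tag
    '# cosmoskit-intervals v1'; line 2 encodes the acquisition schedule as
    '# schedule: frame_duration=..;green_block_length=..;red_interleave_length=..;total_duration=..'.
    One CSV table follows with a record_type column separating location
    metadata rows from interval rows.
  columns:
    record_type: "'location' (metadata row) or 'interval' (binding interval)"
    location_id: unique surface-location identifier
    construct: construct name; 'no_RNA' marks control locations
    start_s: interval start in seconds (closed); empty on location rows
    end_s: interval end in seconds (open); empty on location rows
    left_censored: interval touches the start of the observation (TRUE/FALSE)
    right_censored: interval touches the end of the observation (TRUE/FALSE)
    label: channel / subcomplex label (e.g. U1, U2, U5)
    n_frames_observed: observed green frames; filled on location rows only
  conventions:
    - intervals are closed on the left, open on the right; dwell = end_s - start_s
    - runs of presence separated only by red-interleave (missing) frames are
      merged; bridged red seconds are included in the dwell but not in
      observed time
    - every location appears as a location row even with zero intervals

panel_traces_csv:
  description: run-length-encoded discretized presence traces (traces.csv)
  columns:
    location_id: surface-location identifier
    state: one of present / absent / missing (missing = red-interleave frame)
    length: run length in frames

panel_truth_csv:
  description: ground-truth event table retained by simulate_panel()
  columns:
    location_id: surface-location identifier
    construct: construct name
    arrival_s: binding-event arrival time (s)
    departure_s: departure time (s; censored at total_duration)
    labeled: event carries a dye (TRUE/FALSE)
    specific: specific (splice-site-dependent) event vs nonspecific surface event
    bleached_at_s: wall time of photobleaching, empty if the dye survived
    visible_until_s: min(departure, bleach); empty for unlabeled events
    n_visible_frames: green frames in which the event is visible under the
      >=50%-frame-overlap rule

mat_container:
  description: >
    MAT v5 single-file container written by write_imscroll_intervals();
    struct variable 'Intervals'.
  fields:
    CumulativeIntervalArray: numeric matrix, one row per interval, columns
      [aoi, start_frame, end_frame, start_s, end_s, left_censored, right_censored]
    LocationIDs: cell array of location ids (one per AOI)
    AOIClasses: cell array of construct names (one per AOI)
    Labels: cell array of channel labels (one per interval)
    FramesObserved: observed green frames per AOI
    Schedule: "[frame_duration, green_block_length, red_interleave_length, total_duration]"
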