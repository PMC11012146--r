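kk_major_profile.csv, kk_minor_profile.csv
  Plain-text transcription of the Krumhansl & Kessler (1982) probe-tone
  rating profiles for major and minor keys (mean ratings, semitone offsets
  0-11 from the tonic). Loaded by kk_profiles() and used as the empirical
  fitting target for the key-affinity model.

User-supplied fixtures (not shipped):
  Scalar inter-key distance tables derived from the Krumhansl-Kessler
  4-D toroidal embedding, and perceived triadic-distance ratings
  (Milne & Holland 2016), can be supplied in the same CSV schema
  (semitone_offset,value per 12-entry panel) and loaded with
  load_profile_fixture() for use with fit_profile_model() and
  score_distance_fixture().
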