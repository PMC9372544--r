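{
  "name": "possession_table",
  "description": "One row per ball possession (an uninterrupted spell of one team's ball control) of a small-sided match divided into three 10-minute thirds.",
  "dialect": {
    "encoding": "UTF-8",
    "delimiter": ",",
    "decimal_separator": ".",
    "header": true
  },
  "fields": [
    {"name": "match_id", "type": "string", "description": "Match identifier."},
    {"name": "team_id", "type": "string", "description": "Team identifier, unique within the experiment."},
    {"name": "condition", "type": "string", "enum": ["wR", "Sy", "nS"], "description": "Acoustic condition of the third: without rhythm, synchronous 140 bpm, or non-synchronous per-player tempi."},
    {"name": "order_index", "type": "integer", "minimum": 0, "description": "Position of the possession within the third."},
    {"name": "n_passes", "type": "integer", "minimum": 0, "description": "Completed passes during the possession."},
    {"name": "n_contacts", "type": "integer", "minimum": 1, "description": "Ball contacts during the possession; n_passes <= n_contacts."},
    {"name": "goal", "type": "integer", "enum": [0, 1], "description": "Whether the possession ended with a goal."}
  ]
}
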