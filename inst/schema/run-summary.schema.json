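{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "rpsim run summary",
  "type": "object",
  "required": ["config", "seed", "outcome", "final_step", "stabilization",
               "recorded_steps"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["world", "kinetics", "mutation", "species", "init", "run"],
      "properties": {
        "world": {
          "type": "object",
          "required": ["width", "height"],
          "properties": {
            "width": {"type": "number", "exclusiveMinimum": 0},
            "height": {"type": "number", "exclusiveMinimum": 0}
          }
        },
        "kinetics": {
          "type": "object",
          "required": ["d", "D", "D_complex", "K", "dt", "radius", "n_max"]
        },
        "mutation": {"type": "object", "required": ["delta"]},
        "species": {
          "type": "object",
          "required": ["replicase", "parasite"]
        },
        "init": {
          "type": "object",
          "required": ["n_replicases", "n_parasites", "placement",
                       "disc_radius"]
        },
        "run": {
          "type": "object",
          "required": ["max_steps", "decay_mode", "offspring_offset"]
        }
      }
    },
    "seed": {"type": "integer"},
    "outcome": {
      "type": "string",
      "enum": ["survived", "extinct_parasites", "extinct_replicases",
               "extinct_both"]
    },
    "final_step": {"type": "integer", "minimum": 0},
    "stabilization": {
      "type": "object",
      "required": ["a_R", "l_R", "a_P", "l_P"],
      "properties": {
        "a_R": {"type": ["integer", "null"]},
        "l_R": {"type": ["integer", "null"]},
        "a_P": {"type": ["integer", "null"]},
        "l_P": {"type": ["integer", "null"]}
      }
    },
    "recorded_steps": {"type": "integer", "minimum": 0}
  }
}
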