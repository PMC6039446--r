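{
  "name": "four_state",
  "states": [
    { "label": "1", "occupancy": "S1,S3 (two ions in the filter)" },
    { "label": "2", "occupancy": "S1,S3 + ion at the inner mouth/cavity" },
    { "label": "3", "occupancy": "S0,S2,S4 (three ions, outermost site S0 occupied)" },
    { "label": "5", "occupancy": "S2,S4 (two ions in the filter)" }
  ],
  "edges": [
    { "from": "1", "to": "2", "param": "k12", "kind": "bind_internal", "eyring_group": null },
    { "from": "2", "to": "1", "param": "k21", "kind": "plain", "eyring_group": null },
    { "from": "2", "to": "3", "param": "k23", "kind": "eyring", "eyring_group": "g23" },
    { "from": "3", "to": "2", "param": "k32", "kind": "eyring", "eyring_group": "g23" },
    { "from": "3", "to": "5", "param": "k35", "kind": "plain", "eyring_group": null },
    { "from": "5", "to": "3", "param": "k53", "kind": "bind_external", "eyring_group": null },
    { "from": "5", "to": "1", "param": "k51", "kind": "eyring", "eyring_group": "g51" },
    { "from": "1", "to": "5", "param": "k15", "kind": "eyring", "eyring_group": "g51" }
  ],
  "transport_cycle": ["1", "2", "3", "5"],
  "note": "4-state cycle obtained from the 5-state model by removing the outer-mouth binding state: external release (3->5) is condition-independent and rebinding (5->3) is proportional to the external K+ activity."
}
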