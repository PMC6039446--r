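{
  "name": "five_state_roux",
  "states": [
    { "label": "1", "occupancy": "S1,S3 (two ions in the filter)" },
    { "label": "2", "occupancy": "S1,S3 + ion at the inner mouth/cavity" },
    { "label": "3", "occupancy": "S0,S2,S4 (three ions, outermost site S0 occupied)" },
    { "label": "4", "occupancy": "S2,S4 + ion in the outer pore mouth (outside S0)" },
    { "label": "5", "occupancy": "S2,S4 (two ions in the filter)" }
  ],
  "edges": [
    { "from": "1", "to": "2", "param": "k12", "kind": "bind_internal", "eyring_group": null },
    { "from": "2", "to": "1", "param": "k21", "kind": "plain", "eyring_group": null },
    { "from": "2", "to": "3", "param": "k23", "kind": "eyring", "eyring_group": "g23" },
    { "from": "3", "to": "2", "param": "k32", "kind": "eyring", "eyring_group": "g23" },
    { "from": "3", "to": "4", "param": "k34", "kind": "plain", "eyring_group": null },
    { "from": "4", "to": "3", "param": "k43", "kind": "plain", "eyring_group": null },
    { "from": "4", "to": "5", "param": "k45", "kind": "plain", "eyring_group": null },
    { "from": "5", "to": "4", "param": "k54", "kind": "bind_external", "eyring_group": null },
    { "from": "5", "to": "1", "param": "k51", "kind": "eyring", "eyring_group": "g51" },
    { "from": "1", "to": "5", "param": "k15", "kind": "eyring", "eyring_group": "g51" }
  ],
  "transport_cycle": ["1", "2", "3", "4", "5"],
  "note": "5-state ion hopping cycle: internal binding (1->2), concerted voltage-dependent translocation through the filter centre (2<->3), S0 ion stepping to the outer mouth (3<->4), external release/rebinding (4<->5), and a second voltage-dependent filter shift (5<->1). Forward cycle traversal moves one charge outward."
}
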