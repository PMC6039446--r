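{
  "name": "hard_knock_on",
  "states": [
    { "label": "1", "occupancy": "S1,S2,S3 (contiguous three-ion column)" },
    { "label": "2", "occupancy": "S1,S2,S3 + ion at the inner mouth/cavity" },
    { "label": "3", "occupancy": "S0,S1,S2,S4 (column pushed outward, S0 occupied)" },
    { "label": "4", "occupancy": "S1,S2,S3 + ion in the outer pore mouth" },
    { "label": "5", "occupancy": "S2,S3,S4 (contiguous three-ion column, shifted inward)" }
  ],
  "edges": [
    { "from": "1", "to": "2", "param": "k12", "kind": "bind_internal", "eyring_group": null },
    { "from": "2", "to": "1", "param": "k21", "kind": "plain", "eyring_group": null },
    { "from": "2", "to": "3", "param": "k23", "kind": "eyring", "eyring_group": "gA" },
    { "from": "3", "to": "2", "param": "k32", "kind": "eyring", "eyring_group": "gA" },
    { "from": "3", "to": "4", "param": "k34", "kind": "eyring", "eyring_group": "gB" },
    { "from": "4", "to": "3", "param": "k43", "kind": "eyring", "eyring_group": "gB" },
    { "from": "4", "to": "5", "param": "k45", "kind": "plain", "eyring_group": null },
    { "from": "5", "to": "4", "param": "k54", "kind": "bind_external", "eyring_group": null },
    { "from": "5", "to": "1", "param": "k51", "kind": "plain", "eyring_group": null },
    { "from": "1", "to": "5", "param": "k15", "kind": "plain", "eyring_group": null }
  ],
  "transport_cycle": ["1", "2", "3", "4", "5"],
  "note": "APPROXIMATE direct knock-on cycle: ions move in direct contact, and the two concerted translocation steps that push the column through the filter centre (2<->3, 3<->4) carry the voltage dependence; serial steps that share no independent condition dependence are merged. The exact edge-by-edge assignment of the original scheme is not published in reusable form; this spec is a best-effort cyclic reading and is marked approximate."
}
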