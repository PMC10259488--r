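vehicle: 2% saccharine
day_offset_minutes: 0.0
days:
- day: 1
  concentration: 0.0
  side: none
- day: 2
  concentration: 0.0
  side: none
- day: 3
  concentration: 50.0
  side: left
- day: 4
  concentration: 50.0
  side: left
- day: 5
  concentration: 100.0
  side: right
- day: 6
  concentration: 100.0
  side: right
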