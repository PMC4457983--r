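# Default behavioural-knowledge repository.
#
# Parameters (P_*) encode the domain knowledge the rules and the circadian
# windows reference: room constraints (cooking can only take place in the
# kitchen), channel thresholds (humidity rises while grooming), duration
# bounds (sleeping has a minimum duration) and mealtime/evening clock
# windows. All values are tunable; units are given per parameter.

parameters:
  equality_tolerance:
    value: 0.5
    units: channel units
    description: half-width for the '=' comparator on continuous summaries
  P_bedroom: {value: bedroom, units: room, description: sleeping room}
  P_bathroom: {value: bathroom, units: room, description: hygiene room}
  P_kitchen: {value: kitchen, units: room, description: cooking room}
  P_dining: {value: dining_room, units: room, description: meal room}
  P_living: {value: living_room, units: room, description: living room}
  P_occupancy_pir:
    value: 0.15
    units: V
    description: mean PIR level above which a room counts as occupied
  P_sleep_min_duration:
    value: 180
    units: min
    description: minimum duration for the ADL sleeping
  P_groom_humidity_slope:
    value: 0.1
    units: g/m^3 per min
    description: humidity rise separating grooming from simple toileting
  P_groom_min_duration: {value: 5, units: min, description: grooming lower bound}
  P_groom_max_duration: {value: 40, units: min, description: grooming upper bound}
  P_toilet_max_duration: {value: 20, units: min, description: toileting upper bound}
  P_evening_h:
    value: 21
    units: decimal hour
    description: start of the pre-bed evening window
  P_cooking_temp_slope:
    value: 0.03
    units: degC per min
    description: kitchen temperature rise indicating cooking
  P_cooking_min_duration: {value: 15, units: min, description: cooking lower bound}
  P_meal_min_duration: {value: 10, units: min, description: eating lower bound}
  P_meal_max_duration: {value: 90, units: min, description: eating upper bound}
  P_meal_window_start: {value: 10, units: decimal hour, description: earliest mealtime}
  P_meal_window_end: {value: 21, units: decimal hour, description: latest mealtime}
  P_tv_min_duration: {value: 30, units: min, description: watching TV lower bound}
  P_tv_evening_h: {value: 18.5, units: decimal hour, description: TV evening window start}
  P_tv_lux_mean: {value: 20, units: lx, description: luminescence from a running TV}
  P_seated_min_duration: {value: 20, units: min, description: seated activity lower bound}
  P_seated_max_duration: {value: 180, units: min, description: seated activity upper bound}

# Rules: conjunctions of predicates over segment summaries. 'must' rules
# are hard requirements (a top-level rule such as the room constraint);
# 'likely' rules derive supporting facts. Conflict resolution prefers
# must over likely, then higher priority, then more specific rules.
rules:
  - id: bedroom_presence
    level: likely
    priority: 1
    conclusion: {fact: bedroom_occupied}
    when:
      - {summary: room, op: "=", param: P_bedroom}
      - {summary: mean, channel: pir, op: ">", param: P_occupancy_pir}
  - id: sleeping_main
    level: must
    priority: 10
    conclusion: {adl: sleeping}
    when:
      - {fact: bedroom_occupied}
      - {summary: duration, op: ">=", param: P_sleep_min_duration}
  - id: bathroom_presence
    level: likely
    priority: 1
    conclusion: {fact: bathroom_occupied}
    when:
      - {summary: room, op: "=", param: P_bathroom}
      - {summary: mean, channel: pir, op: ">", param: P_occupancy_pir}
  - id: grooming_humidity
    level: must
    priority: 8
    conclusion: {adl: grooming}
    when:
      - {fact: bathroom_occupied}
      - {summary: slope, channel: humidity, op: ">", param: P_groom_humidity_slope}
      - {summary: duration, op: ">=", param: P_groom_min_duration}
      - {summary: duration, op: "<=", param: P_groom_max_duration}
  - id: toileting_main
    level: must
    priority: 6
    conclusion: {adl: toileting}
    when:
      - {fact: bathroom_occupied}
      - {summary: slope, channel: humidity, op: "<=", param: P_groom_humidity_slope}
      - {summary: duration, op: "<=", param: P_toilet_max_duration}
      - {summary: clock_start, op: "<", param: P_evening_h}
  - id: ready_for_bed
    level: must
    priority: 7
    conclusion: {adl: getting_ready_for_bed}
    when:
      - {fact: bathroom_occupied}
      - {summary: clock_start, op: ">=", param: P_evening_h}
      - {summary: duration, op: "<=", param: P_groom_max_duration}
  - id: kitchen_presence
    level: likely
    priority: 1
    conclusion: {fact: kitchen_occupied}
    when:
      - {summary: room, op: "=", param: P_kitchen}
      - {summary: mean, channel: pir, op: ">", param: P_occupancy_pir}
  - id: cooking_main
    level: must
    priority: 9
    conclusion: {adl: cooking}
    when:
      - {fact: kitchen_occupied}
      - {summary: slope, channel: temperature, op: ">", param: P_cooking_temp_slope}
      - {summary: duration, op: ">=", param: P_cooking_min_duration}
  - id: eating_main
    level: must
    priority: 5
    conclusion: {adl: eating}
    when:
      - {summary: room, op: "=", param: P_dining}
      - {summary: mean, channel: pir, op: ">", param: P_occupancy_pir}
      - {summary: duration, op: ">=", param: P_meal_min_duration}
      - {summary: duration, op: "<=", param: P_meal_max_duration}
      - {summary: clock_start, op: ">=", param: P_meal_window_start}
      - {summary: clock_start, op: "<", param: P_meal_window_end}
  - id: tv_main
    level: must
    priority: 5
    conclusion: {adl: watching_tv}
    when:
      - {summary: room, op: "=", param: P_living}
      - {summary: mean, channel: pir, op: ">", param: P_occupancy_pir}
      - {summary: clock_start, op: ">=", param: P_tv_evening_h}
      - {summary: duration, op: ">=", param: P_tv_min_duration}
      - {summary: mean, channel: luminescence, op: ">", param: P_tv_lux_mean}
  - id: seated_main
    level: must
    priority: 4
    conclusion: {adl: seated_activity}
    when:
      - {summary: room, op: "=", param: P_living}
      - {summary: mean, channel: pir, op: ">", param: P_occupancy_pir}
      - {summary: clock_start, op: "<", param: P_tv_evening_h}
      - {summary: duration, op: ">=", param: P_seated_min_duration}
      - {summary: duration, op: "<=", param: P_seated_max_duration}

# Circadian parameter windows used by the rhythm classifier: per ADL the
# admissible rooms, duration range (minutes), and the clock window (centre
# and half-width, decimal hours, circular over 24 h) the recurring
# pattern's temporal emphasis must fall in. min_rel_duration constrains
# duration relative to the longest co-occurring pattern (sleeping is the
# dominant nightly pattern).
adl_windows:
  sleeping:
    rooms: [bedroom]
    duration_min: [180, 720]
    clock_center_h: 2.5
    clock_halfwidth_h: 5.5
    min_rel_duration: 0.5
  grooming:
    rooms: [bathroom]
    duration_min: [5, 40]
    clock_center_h: 7.6
    clock_halfwidth_h: 2.5
  toileting:
    rooms: [bathroom]
    duration_min: [2, 20]
    clock_center_h: 13.6
    clock_halfwidth_h: 3
  getting_ready_for_bed:
    rooms: [bathroom]
    duration_min: [2, 40]
    clock_center_h: 22.8
    clock_halfwidth_h: 1.6
  cooking:
    rooms: [kitchen]
    duration_min: [15, 90]
    clock_center_h: 11.9
    clock_halfwidth_h: 2
  eating:
    rooms: [dining_room]
    duration_min: [10, 90]
    clock_center_h: 12.7
    clock_halfwidth_h: 2
  watching_tv:
    rooms: [living_room]
    duration_min: [30, 240]
    clock_center_h: 20.8
    clock_halfwidth_h: 2.2
  seated_activity:
    rooms: [living_room]
    duration_min: [20, 180]
    clock_center_h: 15.5
    clock_halfwidth_h: 2.5
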