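<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic, minimal PhysiCell-style settings skeleton bundled for the
     desk-scale biorobots demonstration. Not a real PhysiCell export. -->
<PhysiCell_settings version="sample">
  <domain>
    <x_min>-500</x_min>
    <x_max>500</x_max>
    <y_min>-500</y_min>
    <y_max>500</y_max>
    <use_2D>true</use_2D>
  </domain>
  <overall>
    <max_time units="min">2880</max_time>
    <time_units>min</time_units>
    <space_units>micron</space_units>
  </overall>
  <parallel>
    <omp_num_threads>1</omp_num_threads>
  </parallel>
  <save>
    <folder>output</folder>
    <full_data>
      <interval units="min">60</interval>
      <enable>true</enable>
    </full_data>
  </save>
  <user_parameters>
    <random_seed type="int" units="dimensionless">0</random_seed>
    <attached_worker_migration_bias type="double" units="dimensionless">1.0</attached_worker_migration_bias>
    <unattached_worker_migration_bias type="double" units="dimensionless">0.5</unattached_worker_migration_bias>
    <number_of_workers type="int" units="dimensionless">5</number_of_workers>
    <number_of_cargo type="int" units="dimensionless">10</number_of_cargo>
    <number_of_steps type="int" units="dimensionless">500</number_of_steps>
    <step_length type="double" units="micron">1.0</step_length>
    <delivery_radius type="double" units="micron">2.0</delivery_radius>
    <arena_size type="double" units="micron">100.0</arena_size>
  </user_parameters>
</PhysiCell_settings>
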