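<?xml version="1.0" encoding="UTF-8"?>
<neuroml xmlns="http://www.neuroml.org/schema/neuroml2">
  <cell id="bitufted_1">
    <morphology id="morph_bitufted">
      <segment id="0" name="soma_0">
        <proximal x="0.000000" y="-6.671712" z="0.000000" diameter="13.343424"/>
        <distal x="0.000000" y="6.671712" z="0.000000" diameter="13.343424"/>
      </segment>
      <segment id="1" name="ais_1">
        <parent segment="0"/>
        <proximal x="0.000000" y="-6.671712" z="0.000000" diameter="1.510928"/>
        <distal x="1.474761" y="-18.714281" z="-1.077755" diameter="1.510928"/>
      </segment>
      <segment id="2" name="ais_2">
        <parent segment="1"/>
        <proximal x="1.474761" y="-18.714281" z="-1.077755" diameter="1.510928"/>
        <distal x="2.949522" y="-30.756850" z="-2.155510" diameter="1.510928"/>
      </segment>
      <segment id="3" name="basal_3">
        <parent segment="0"/>
        <proximal x="1.814965" y="6.404844" z="0.442294" diameter="1.552956"/>
        <distal x="18.692332" y="65.963525" z="4.555189" diameter="1.087069"/>
      </segment>
      <segment id="4" name="basal_4">
        <parent segment="3"/>
        <proximal x="18.692332" y="65.963525" z="4.555189" diameter="1.087069"/>
        <distal x="34.695826" y="116.171086" z="81.258087" diameter="0.621182"/>
      </segment>
      <segment id="5" name="basal_5">
        <parent segment="3"/>
        <proximal x="18.692332" y="65.963525" z="4.555189" diameter="1.087069"/>
        <distal x="61.384879" y="122.644778" z="-55.651352" diameter="0.621182"/>
      </segment>
      <segment id="6" name="basal_6">
        <parent segment="0"/>
        <proximal x="-0.492521" y="-6.404844" z="1.801983" diameter="1.643175"/>
        <distal x="-5.396078" y="-70.171702" z="19.742595" diameter="1.150222"/>
      </segment>
      <segment id="7" name="basal_7">
        <parent segment="6"/>
        <proximal x="-5.396078" y="-70.171702" z="19.742595" diameter="1.150222"/>
        <distal x="-70.976469" y="-145.041055" z="24.332589" diameter="0.657270"/>
      </segment>
      <segment id="8" name="basal_8">
        <parent segment="6"/>
        <proximal x="-5.396078" y="-70.171702" z="19.742595" diameter="1.150222"/>
        <distal x="31.612892" y="-158.150715" z="48.331146" diameter="0.657270"/>
      </segment>
      <segment id="9" name="basal_9">
        <parent segment="0"/>
        <proximal x="-1.859392" y="6.404844" z="-0.179950" diameter="1.580806"/>
        <distal x="-22.675315" y="78.107170" z="-2.194497" diameter="1.106564"/>
      </segment>
      <segment id="10" name="basal_10">
        <parent segment="9"/>
        <proximal x="-22.675315" y="78.107170" z="-2.194497" diameter="1.106564"/>
        <distal x="-37.860582" y="179.452175" z="-47.475981" diameter="0.632322"/>
      </segment>
      <segment id="11" name="basal_11">
        <parent segment="9"/>
        <proximal x="-22.675315" y="78.107170" z="-2.194497" diameter="1.106564"/>
        <distal x="-77.685663" y="134.773491" z="77.269990" diameter="0.632322"/>
      </segment>
      <segment id="12" name="basal_12">
        <parent segment="0"/>
        <proximal x="0.144572" y="-6.404844" z="-1.862477" diameter="1.624268"/>
        <distal x="1.533263" y="-67.926576" z="-19.752499" diameter="1.136987"/>
      </segment>
      <segment id="13" name="basal_13">
        <parent segment="12"/>
        <proximal x="1.533263" y="-67.926576" z="-19.752499" diameter="1.136987"/>
        <distal x="34.288969" y="-157.256727" z="-33.453741" diameter="0.649707"/>
      </segment>
      <segment id="14" name="basal_14">
        <parent segment="12"/>
        <proximal x="1.533263" y="-67.926576" z="-19.752499" diameter="1.136987"/>
        <distal x="-67.977229" y="-123.859849" z="-55.533732" diameter="0.649707"/>
      </segment>
      <segmentGroup id="soma_group">
        <member segment="0"/>
      </segmentGroup>
      <segmentGroup id="axon_group">
        <member segment="1"/>
        <member segment="2"/>
      </segmentGroup>
      <segmentGroup id="dendrite_group">
        <member segment="3"/>
        <member segment="4"/>
        <member segment="5"/>
        <member segment="6"/>
        <member segment="7"/>
        <member segment="8"/>
        <member segment="9"/>
        <member segment="10"/>
        <member segment="11"/>
        <member segment="12"/>
        <member segment="13"/>
        <member segment="14"/>
      </segmentGroup>
    </morphology>
  </cell>
</neuroml>
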