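<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic single-compartment SBML example of the supported import
     subset: a birth-death process with explicit kinetic laws. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="birth_death_synthetic">
    <listOfCompartments>
      <compartment id="cell" size="10"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="X" name="protein X" compartment="cell"
               initialConcentration="10"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k" value="5"/>
      <parameter id="d" value="0.5"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="birth" reversible="false">
        <listOfProducts>
          <speciesReference species="X" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <ci> k </ci>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="death" reversible="false">
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci> d </ci>
              <ci> X </ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
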