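{"type":"FeatureCollection","properties":{"specimen_id":"synthetic_demo"},"features":[{"type":"Feature","properties":{"role":"tumor"},"geometry":{"type":"Polygon","coordinates":[[[371.602388541784,268.97743825546],[371.014535989412,280.94345185354],[369.256639673727,292.794226199383],[366.345629097214,304.415631857745],[362.309538883045,315.69574833923],[357.187238786333,326.525941955782],[351.028059357143,336.801912022487],[343.89131686033,346.424695330188],[335.845742027477,355.301619215281],[326.968818142384,363.347194048134],[317.346034834683,370.483936544947],[307.070064767978,376.643115974137],[296.239871151426,381.765416070849],[284.959754669941,385.801506285018],[273.338349011579,388.712516861531],[261.487574665736,390.470413177216],[249.521561067656,391.058265729588],[237.555547469575,390.470413177216],[225.704773123733,388.712516861531],[214.083367465371,385.801506285018],[202.803250983886,381.765416070849],[191.973057367334,376.643115974137],[181.697087300628,370.483936544947],[172.074303992928,363.347194048134],[163.197380107835,355.301619215281],[155.151805274982,346.424695330188],[148.015062778168,336.801912022487],[141.855883348979,326.525941955782],[136.733583252267,315.69574833923],[132.697493038097,304.415631857745],[129.786482461584,292.794226199383],[128.0285861459,280.94345185354],[127.440733593527,268.97743825546],[128.0285861459,257.011424657379],[129.786482461584,245.160650311537],[132.697493038097,233.539244653175],[136.733583252267,222.25912817169],[141.855883348979,211.428934555138],[148.015062778168,201.152964488433],[155.151805274982,191.530181180732],[163.197380107835,182.653257295639],[172.074303992928,174.607682462786],[181.697087300628,167.470939965972],[191.973057367334,161.311760536783],[202.803250983886,156.189460440071],[214.083367465371,152.153370225902],[225.704773123733,149.242359649388],[237.555547469575,147.484463333704],[249.521561067656,146.896610781331],[261.487574665736,147.484463333704],[273.338349011579,149.242359649388],[284.959754669941,152.153370225902],[296.239871151426,156.189460440071],[307.070064767978,161.311760536783],[317.346034834683,167.470939965972],[326.968818142384,174.607682462786],[335.845742027477,182.653257295639],[343.89131686033,191.530181180732],[351.028059357143,201.152964488433],[357.187238786333,211.428934555138],[362.309538883045,222.25912817169],[366.345629097214,233.539244653175],[369.256639673727,245.160650311537],[371.014535989412,257.011424657379],[371.602388541784,268.97743825546]]]}},{"type":"Feature","properties":{"role":"stroma"},"geometry":{"type":"Polygon","coordinates":[[[0,0],[400,0],[400,400],[0,400],[0,0]]]}}]}
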