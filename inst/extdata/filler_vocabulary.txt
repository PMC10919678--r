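patient
was
then
placed
under
general
anesthesia
prepped
draped
usual
sterile
fashion
incision
made
carried
down
through
skin
subcutaneous
tissue
dissection
performed
care
taken
protect
identified
exposed
using
blunt
sharp
retractor
hemostasis
achieved
with
electrocautery
irrigated
copious
saline
wound
closed
layers
interrupted
sutures
nylon
vicryl
applied
dressing
tolerated
procedure
well
recovery
room
stable
condition
informed
consent
obtained
risks
benefits
discussed
timeout
confirmed
site
laterality
antibiotics
given
tourniquet
inflated
deflated
elevated
limb
extremity
position
supine
prone
lateral
table
standard
approach
deep
superficial
layer
fascia
muscle
tendon
ligament
capsule
joint
bone
cartilage
fracture
reduction
fixation
alignment
fluoroscopy
imaging
views
satisfactory
placement
hardware
plate
screws
wire
pin
rod
nail
implant
removed
inserted
drill
guide
reamed
depth
measured
length
width
distal
proximal
medial
anterior
posterior
superior
inferior
left
right
knee
shoulder
elbow
wrist
hip
ankle
foot
hand
finger
thumb
femur
tibia
fibula
humerus
radius
ulna
patella
meniscus
labrum
rotator
cuff
portal
arthroscope
camera
inspection
revealed
intact
normal
examination
range
motion
stability
tested
found
noted
small
large
moderate
mild
severe
chronic
acute
degenerative
tear
repair
debridement
excision
release
graft
harvested
prepared
passed
secured
tensioned
anchor
suture
knots
tied
probe
shaver
burr
curette
osteotome
mallet
clamp
forceps
scalpel
blade
needle
syringe
injection
local
anesthetic
marcaine
lidocaine
epinephrine
sponge
count
correct
specimen
sent
pathology
culture
drain
splint
cast
brace
sling
crutches
weight
bearing
instructions
followup
clinic
weeks
days
blood
loss
minimal
complications
none
estimated
history
diagnosis
preoperative
postoperative
indication
plan
technique
details
attention
turned
next
portion
aspect
region
area
surface
margin
edge
border
midline
curvilinear
longitudinal
transverse
oblique
centered
over
approximately
cm
mm
level
angle
degrees
flexion
extension
rotation
varus
valgus
gentle
manipulation
traction
countertraction
visualization
excellent
adequate
maintained
throughout
remainder
uneventful
awakened
extubated
transferred
monitored
vital
signs
within
limits
periarticular
paraarticular
retroarticular
subarticular
supraarticular
infraarticular
interarticular
intraarticular
transarticular
prearticular
postarticular
semiarticular
hemiarticular
neoarticular
rearticular
dearticular
nonarticular
microarticular
macroarticular
periosseous
paraosseous
retroosseous
subosseous
supraosseous
infraosseous
interosseous
intraosseous
transosseous
preosseous
postosseous
semiosseous
hemiosseous
neoosseous
reosseous
deosseous
nonosseous
microosseous
macroosseous
peritendinous
paratendinous
retrotendinous
subtendinous
supratendinous
infratendinous
intertendinous
intratendinous
transtendinous
pretendinous
posttendinous
semitendinous
hemitendinous
neotendinous
retendinous
detendinous
nontendinous
microtendinous
macrotendinous
pericapsular
paracapsular
retrocapsular
subcapsular
supracapsular
infracapsular
intercapsular
intracapsular
transcapsular
precapsular
postcapsular
semicapsular
hemicapsular
neocapsular
recapsular
decapsular
noncapsular
microcapsular
macrocapsular
pericortical
paracortical
retrocortical
subcortical
supracortical
infracortical
intercortical
intracortical
transcortical
precortical
postcortical
semicortical
hemicortical
neocortical
recortical
decortical
noncortical
microcortical
macrocortical
perimuscular
paramuscular
retromuscular
submuscular
supramuscular
inframuscular
intermuscular
intramuscular
transmuscular
premuscular
postmuscular
semimuscular
hemimuscular
neomuscular
remuscular
demuscular
nonmuscular
micromuscular
macromuscular
periligamentous
paraligamentous
retroligamentous
subligamentous
supraligamentous
infraligamentous
interligamentous
intraligamentous
transligamentous
preligamentous
postligamentous
semiligamentous
hemiligamentous
neoligamentous
religamentous
deligamentous
nonligamentous
microligamentous
macroligamentous
perisynovial
parasynovial
retrosynovial
subsynovial
suprasynovial
infrasynovial
intersynovial
intrasynovial
transsynovial
presynovial
postsynovial
semisynovial
hemisynovial
neosynovial
resynovial
desynovial
nonsynovial
microsynovial
macrosynovial
perichondral
parachondral
retrochondral
subchondral
suprachondral
infrachondral
interchondral
intrachondral
transchondral
prechondral
postchondral
semichondral
hemichondral
neochondral
rechondral
dechondral
nonchondral
microchondral
macrochondral
periperiosteal
paraperiosteal
retroperiosteal
subperiosteal
supraperiosteal
infraperiosteal
interperiosteal
intraperiosteal
transperiosteal
preperiosteal
postperiosteal
semiperiosteal
hemiperiosteal
neoperiosteal
reperiosteal
deperiosteal
nonperiosteal
microperiosteal
macroperiosteal
perifascial
parafascial
retrofascial
subfascial
suprafascial
infrafascial
interfascial
intrafascial
transfascial
prefascial
postfascial
semifascial
hemifascial
neofascial
refascial
defascial
nonfascial
microfascial
macrofascial
peridermal
paradermal
retrodermal
subdermal
supradermal
infradermal
interdermal
intradermal
transdermal
predermal
postdermal
semidermal
hemidermal
neodermal
redermal
dedermal
nondermal
microdermal
macrodermal
perivascular
paravascular
retrovascular
subvascular
supravascular
infravascular
intervascular
intravascular
transvascular
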