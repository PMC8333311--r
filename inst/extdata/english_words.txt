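able
about
acid
across
act
action
add
age
ago
air
all
almost
alone
along
already
also
always
among
animal
answer
appear
apple
area
arm
army
around
art
ask
atom
away
baby
back
bad
ball
band
bank
bar
base
basic
bat
bear
beat
beauty
bed
been
before
began
begin
behind
bell
belt
best
better
big
bird
bit
black
block
blood
blow
blue
board
boat
body
bone
book
born
both
bottom
box
boy
branch
bread
break
bright
bring
broad
brother
brown
build
burn
busy
cat
catch
cause
cell
cent
center
certain
chair
chance
change
character
charge
chart
check
chick
chief
child
choose
circle
city
claim
class
clean
clear
climb
clock
close
cloud
coast
coat
cold
collect
colony
color
column
come
common
company
compare
complete
condition
connect
consider
consonant
contain
continue
control
cook
cool
cope
copy
corn
corner
correct
cost
cotton
could
count
country
course
cover
cow
crease
create
crop
cross
crowd
cry
current
cut
dad
dance
danger
dark
day
dead
deal
dear
death
decide
decimal
deep
degree
depend
describe
desert
design
determine
develop
dictionary
did
die
differ
difficult
direct
discuss
distant
divide
division
doctor
dog
dollar
done
door
double
down
draw
dream
dress
drink
drive
drop
dry
duck
during
each
ear
early
earth
ease
east
eat
edge
effect
egg
eight
either
electric
element
else
end
enemy
energy
engine
enough
enter
equal
equate
especially
even
evening
event
ever
every
exact
example
except
excite
exercise
expect
experience
experiment
eye
face
fact
factor
fair
fall
family
famous
far
farm
fast
fat
father
favor
fear
feed
feel
feet
fell
felt
few
field
fig
fight
figure
fill
final
find
fine
finger
finish
fire
first
fish
fit
five
flat
floor
flow
flower
fly
follow
food
foot
force
forest
form
forward
found
four
fraction
free
fresh
friend
from
front
fruit
full
fun
game
garden
gas
gather
gave
general
gentle
get
girl
give
glad
glass
gold
gone
good
got
govern
grand
grass
gray
great
green
grew
ground
group
grow
guess
guide
gun
hair
half
hand
happen
happy
hard
hat
head
hear
heard
heart
heat
heavy
held
help
high
hill
history
hit
hold
hole
home
hope
horse
hot
hour
house
huge
human
hundred
hunt
hurry
ice
idea
imagine
impact
inch
include
indicate
industry
insect
instant
instrument
interest
invent
iron
island
job
join
joy
jump
keep
key
killer
kind
king
knew
know
lady
lake
land
language
large
last
late
laugh
law
lay
lead
learn
least
leave
left
leg
less
let
letter
level
lie
life
lift
light
like
line
liquid
list
listen
little
live
locate
log
lone
long
look
lost
lot
loud
love
low
machine
made
magnet
main
major
make
man
many
map
mark
market
mask
mass
master
match
material
matter
may
mean
meant
measure
meat
meet
melody
men
metal
method
middle
might
mile
milk
million
mind
mine
minute
miss
mix
modern
molecule
moment
money
month
moon
morning
mother
mountain
mount
mouth
move
much
multiply
music
must
name
nation
natural
nature
near
necessary
neck
need
neighbor
never
new
next
night
nine
noise
noon
north
nose
note
nothing
notice
noun
number
numeral
object
observe
occur
ocean
offer
office
often
oil
old
one
open
operate
opposite
orca
order
organ
original
out
oxygen
page
paint
pair
paper
paragraph
parent
part
particular
party
pass
past
path
pattern
pay
people
perhaps
period
person
phrase
pick
picture
piece
pitch
place
plain
plan
plane
planet
plant
play
please
plural
poem
point
poor
populate
port
pose
position
possible
post
pound
power
practice
prepare
present
press
pretty
print
probable
problem
process
produce
product
proper
property
protect
prove
provide
pull
push
put
quart
question
quick
quiet
quite
race
radio
rail
rain
raise
ran
range
rank
rather
reach
read
ready
real
reason
receive
record
red
region
remember
repeat
reply
represent
rest
result
rich
ride
right
ring
rise
river
road
rock
roll
room
root
rope
rose
round
row
rub
rule
run
safe
said
sail
salt
same
sand
sat
save
saw
say
scale
school
science
score
sea
search
season
seat
second
section
see
seed
seem
segment
select
self
sell
send
sense
sent
sentence
separate
serve
set
settle
seven
several
shall
shape
share
sharp
sheet
shell
shine
ship
shoe
shop
shore
short
should
shoulder
shout
show
side
sight
sign
silent
silver
simple
since
sing
single
sister
sit
six
size
skill
skin
sky
slave
sleep
slip
slow
small
smell
smile
snow
soft
soil
soldier
solution
solve
some
son
song
soon
sound
south
space
speak
special
speech
speed
spell
spend
spoke
spot
spread
spring
square
stand
star
start
state
station
stay
stead
steam
steel
step
stick
still
stone
stood
stop
store
story
straight
strange
stream
street
stretch
string
strong
student
study
subject
substance
subtract
success
such
sudden
suffix
sugar
suggest
suit
summer
sun
supply
support
sure
surface
surprise
swim
syllable
symbol
system
table
tail
take
talk
tall
teach
team
teeth
tell
temperature
ten
term
test
thank
them
then
there
thick
thin
thing
think
third
thought
thousand
three
through
throw
thus
tie
time
tiny
tire
together
told
tone
tool
top
total
touch
toward
town
track
trade
train
trap
travel
tree
triangle
trip
trouble
truck
true
try
tube
turn
twenty
two
type
under
unit
until
use
usual
valley
value
vary
verb
very
view
village
visit
voice
vowel
wait
walk
wall
want
war
warm
wash
watch
water
wave
way
wear
weather
week
weight
well
went
west
whale
wheel
where
whether
white
whole
whose
wide
wife
wild
win
wind
window
wing
winter
wire
wish
wonder
wood
word
work
world
would
write
written
wrong
yard
year
yellow
yes
yet
young
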